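## Reaction-profile statistics: turns PMFs, MEP profiles, bootstrap
## ensembles, decay trajectories and separation scans into per-transition
## free energies and barriers, equilibrium constants, reverse-barrier
## frequencies, percent comparisons, decay classes and separation trends.

.rev_barrier_threshold <- 0.005  # eV: smallest reverse barrier we report

#' Equilibrium constant of a transition
#'
#' K = exp(-dG / kB T).
#'
#' @param dG reaction (free) energy, eV
#' @param T temperature, K
#' @return dimensionless K
#' @export
equilibrium_constant <- function(dG, T = 310) {
  stopifnot(T > 0)
  exp(-dG / (dpt_constants$kB * T))
}

## landmark lambda values of the states on the transfer path
.state_lambda <- c(GC = 0, G_minus_C_plus = 0.5, G_plus_C_minus = 0.5,
                   GstarCstar = 1)

#' Extract a reaction profile from a PMF or MEP energy profile
#'
#' Locates stationary points (sign changes of the discrete derivative
#' after light smoothing; for MEP input the refined saddle and endpoint
#' energies are used directly), labels them against the path landmarks,
#' and assembles per-transition statistics: reaction energy, forward and
#' reverse barriers, and equilibrium constants. A reverse barrier below
#' the detection threshold (0.005 eV) is reported as barrier-less
#' (`NA`), never as zero.
#'
#' @param profile a `dpt_pmf`, a `dpt_mep`, or a data.frame with columns
#'   `x` (position in lambda) and `G_eV`
#' @param T temperature, K (for equilibrium constants)
#' @param via which zwitterion the profile's pathway traverses
#' @param energy_kind "free_energy" (thermal/US profile) or
#'   "potential_energy" (frozen MEP profile)
#' @param smooth moving-average half-window applied before stationary
#'   detection (data.frame/PMF input)
#' @param scenario scenario id carried into the result
#' @return a `dpt_profile`: list with `stationary` (state, x, G_eV) and
#'   `transitions` (transition, dG_rxn_eV, dG_fwd_eV, dG_rev_eV, K)
#' @export
analyze_profile <- function(profile, T = 310,
                            via = c("G_minus_C_plus", "G_plus_C_minus"),
                            energy_kind = NULL, smooth = 5,
                            scenario = NULL) {
  via <- match.arg(via)
  if (inherits(profile, "dpt_mep")) {
    if (is.null(energy_kind)) energy_kind <- "potential_energy"
    st <- .stationary_from_mep(profile)
    if (is.null(scenario)) scenario <- "mep"
  } else {
    if (is.null(energy_kind)) energy_kind <- "free_energy"
    df <- if (inherits(profile, "dpt_pmf"))
      data.frame(x = profile$lambda, G_eV = profile$G_eV)
    else data.frame(x = profile[[1]], G_eV = profile[[2]])
    df <- df[is.finite(df$G_eV), ]
    if (nrow(df) < 5) stop("profile too short for stationary analysis")
    st <- .stationary_from_curve(df, smooth, via)
    if (is.null(scenario)) scenario <- "profile"
  }
  trans <- .transitions_from_stationary(st, T, via)
  structure(list(scenario = scenario, stationary = st, transitions = trans,
                 T = T, energy_kind = energy_kind, via = via),
            class = "dpt_profile")
}

## stationary sequence from a sampled 1D curve
.stationary_from_curve <- function(df, smooth, via) {
  g <- df$G_eV
  if (smooth > 1 && nrow(df) > 2 * smooth) {
    k <- rep(1 / smooth, smooth)
    gs <- stats::filter(g, k, sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
  } else gs <- g
  d <- diff(gs)
  sgn <- sign(d); sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1
  ## refine each turn on the raw profile within +-smooth points
  refine <- function(i, minimum) {
    lo <- max(1, i - smooth); hi <- min(nrow(df), i + smooth)
    j <- if (minimum) lo - 1 + which.min(g[lo:hi]) else lo - 1 + which.max(g[lo:hi])
    j
  }
  idx <- c(1, turns, nrow(df))
  kind <- c(TRUE, diff(sgn)[turns - 1] > 0, TRUE)  # TRUE = minimum
  kind[length(kind)] <- gs[nrow(df)] < gs[max(1, nrow(df) - 2)]
  rows <- list()
  for (ii in seq_along(idx)) {
    j <- refine(idx[ii], kind[ii])
    rows[[ii]] <- data.frame(x = df$x[j], G_eV = g[j], minimum = kind[ii])
  }
  st <- do.call(rbind, rows)
  st <- st[!duplicated(st$x), ]
  ## endpoints: first is the GC minimum by construction
  st$minimum[1] <- TRUE
  .label_stationary(st, via)
}

.label_stationary <- function(st, via) {
  st$state <- NA_character_
  mins <- which(st$minimum)
  for (i in mins) {
    st$state[i] <- if (st$x[i] < 0.15) "GC"
    else if (st$x[i] > 0.85) "GstarCstar"
    else via
  }
  maxs <- which(!st$minimum)
  for (i in maxs) {
    before_zw <- st$x[i] <= 0.5
    st$state[i] <- if (before_zw) "TS1" else "TS2"
  }
  ## profile endpoints are the canonical and product states regardless of
  ## local shape (a monotone profile ends at G*C* on a slope, not a TS)
  st$state[1] <- "GC"
  if (st$x[nrow(st)] > 0.85) st$state[nrow(st)] <- "GstarCstar"
  ## collapse duplicated state labels to the extreme representative
  keep <- rep(TRUE, nrow(st))
  for (s in unique(st$state)) {
    j <- which(st$state == s)
    if (length(j) > 1) {
      best <- if (st$minimum[j[1]]) j[which.min(st$G_eV[j])]
      else j[which.max(st$G_eV[j])]
      keep[setdiff(j, best)] <- FALSE
    }
  }
  st <- st[keep, c("state", "x", "G_eV", "minimum")]
  rownames(st) <- NULL
  st
}

.stationary_from_mep <- function(mep) {
  geom <- geometry_refs()
  lam_img <- lambda_of(mep$images[, 1], mep$images[, 2], geom)
  E0 <- mep$energy[1]
  rows <- list(data.frame(state = "GC", x = lam_img[1],
                          G_eV = 0, minimum = TRUE))
  ## interior minimum (zwitterion) from the images
  n <- length(mep$energy)
  int <- 2:(n - 1)
  locmin <- int[int %in% (which(diff(sign(diff(mep$energy))) == 2) + 1)]
  for (i in locmin)
    rows[[length(rows) + 1]] <- data.frame(
      state = mep$via, x = lam_img[i], G_eV = mep$energy[i] - E0,
      minimum = TRUE)
  if (!is.null(mep$saddles) && nrow(mep$saddles)) {
    lam_s <- lambda_of(mep$saddles$r1, mep$saddles$r2, geom)
    for (i in seq_len(nrow(mep$saddles)))
      rows[[length(rows) + 1]] <- data.frame(
        state = if (lam_s[i] <= 0.5) "TS1" else "TS2",
        x = lam_s[i], G_eV = mep$saddles$energy_eV[i] - E0, minimum = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    state = "GstarCstar", x = lam_img[n], G_eV = mep$energy[n] - E0,
    minimum = TRUE)
  st <- do.call(rbind, rows)
  st <- st[order(st$x), ]
  .label_stationary(st, mep$via)
}

.transitions_from_stationary <- function(st, T, via) {
  G <- setNames(st$G_eV, st$state)
  has <- function(s) s %in% st$state
  mkrow <- function(id, from, to, ts) {
    dG <- G[to] - G[from]
    fwd <- if (!is.null(ts) && has(ts)) G[ts] - G[from] else NA_real_
    rev <- if (!is.null(ts) && has(ts)) G[ts] - G[to] else NA_real_
    if (is.finite(rev) && rev < .rev_barrier_threshold) rev <- NA_real_
    data.frame(transition = id, dG_rxn_eV = unname(dG),
               dG_fwd_eV = unname(fwd), dG_rev_eV = unname(rev),
               K = unname(equilibrium_constant(dG, T)))
  }
  out <- list()
  zw <- via
  if (has("GC") && has(zw))
    out$step1 <- mkrow(paste0("GC->", zw), "GC", zw,
                       if (has("TS1")) "TS1")
  if (has(zw) && has("GstarCstar"))
    out$step2 <- mkrow(paste0(zw, "->GstarCstar"), zw, "GstarCstar",
                       if (has("TS2")) "TS2")
  if (has("GC") && has("GstarCstar")) {
    ## without a zwitterion intermediate the overall transition carries the
    ## (highest) barrier itself
    ts_all <- intersect(c("TS1", "TS2"), st$state)
    ts_ov <- if (!has(zw) && length(ts_all))
      ts_all[which.max(G[ts_all])] else NULL
    out$overall <- mkrow("GC->GstarCstar", "GC", "GstarCstar", ts_ov)
  }
  if (!length(out)) {
    ## monotone profile: overall rise only
    out$overall <- data.frame(transition = "GC->GstarCstar",
                              dG_rxn_eV = max(st$G_eV) - min(st$G_eV),
                              dG_fwd_eV = NA_real_, dG_rev_eV = NA_real_,
                              K = equilibrium_constant(max(st$G_eV) - min(st$G_eV), T))
  }
  tr <- do.call(rbind, out)
  rownames(tr) <- NULL
  tr
}

#' Reverse-barrier presence fraction over a profile ensemble
#'
#' Percentage of (typically bootstrap) reaction profiles in which the
#' given transition retains a reverse barrier above the detection
#' threshold.
#'
#' @param profiles list of `dpt_profile` (>= 2)
#' @param transition transition id, e.g. "GC->G_minus_C_plus"
#' @param threshold detection threshold, eV
#' @return percentage in [0, 100]
#' @export
reverse_barrier_fraction <- function(profiles, transition,
                                     threshold = .rev_barrier_threshold) {
  stopifnot(length(profiles) >= 2)
  has_tr <- vapply(profiles, function(p)
    transition %in% p$transitions$transition, NA)
  if (!any(has_tr)) {
    warning("transition '", transition, "' absent from all profiles; ",
            "fraction undefined")
    return(NA_real_)
  }
  present <- vapply(profiles, function(p) {
    tr <- p$transitions
    i <- match(transition, tr$transition)
    ## a profile without the transition has, in particular, no reverse
    ## barrier for it
    isTRUE(!is.na(i) && is.finite(tr$dG_rev_eV[i]) &&
             tr$dG_rev_eV[i] > threshold)
  }, NA)
  100 * mean(present)
}

#' Percent change conventions
#'
#' `percent_reduction(a, b)` = 100 (a - b) / a (how much smaller b is than
#' the baseline a); `percent_relative_increase(a, b)` = 100 (b / a - 1)
#' (how much more frequent b is than a).
#'
#' @param a baseline value
#' @param b comparison value
#' @return percentage
#' @export
percent_reduction <- function(a, b) {
  if (any(a == 0)) stop("undefined: zero baseline")
  100 * (a - b) / a
}

#' @rdname percent_reduction
#' @export
percent_relative_increase <- function(a, b) {
  if (any(a == 0)) stop("undefined: zero baseline")
  100 * (b / a - 1)
}

#' Compare two reaction profiles
#'
#' For every transition present in both profiles, reports each energy
#' quantity under both percent-change conventions (reduction relative to
#' `a`; relative increase of `b` over `a`), plus the plain ratio, so the
#' convention is always explicit in the output.
#'
#' @param a,b `dpt_profile` objects (a is the baseline)
#' @return data.frame (transition, quantity, value_a, value_b,
#'   reduction_pct, relative_increase_pct, ratio)
#' @export
compare_profiles <- function(a, b) {
  ta <- a$transitions; tb <- b$transitions
  common <- intersect(ta$transition, tb$transition)
  if (!length(common)) stop("no matching transition ids")
  rows <- list()
  for (tr in common) {
    ia <- match(tr, ta$transition); ib <- match(tr, tb$transition)
    for (q in c("dG_rxn_eV", "dG_fwd_eV", "dG_rev_eV", "K")) {
      va <- ta[[q]][ia]; vb <- tb[[q]][ib]
      if (!is.finite(va) || !is.finite(vb)) next
      rows[[length(rows) + 1]] <- data.frame(
        transition = tr, quantity = q, value_a = va, value_b = vb,
        reduction_pct = if (va != 0) 100 * (va - vb) / va else NA_real_,
        relative_increase_pct = if (va != 0) 100 * (vb / va - 1) else NA_real_,
        ratio = if (va != 0) vb / va else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a tautomer-decay trajectory
#'
#' Records the first-passage time into the GC basin (lambda below
#' `stop_lambda`) and classifies the decay path by which region the
#' trajectory occupies when it first crosses the anti-diagonal separatrix
#' u1 + u2 = 1 (the line through both zwitterions and the synchronous
#' maximum): nearest landmark among G-C+, G+C-, and the central
#' synchronous maximum.
#'
#' @param traj a `dpt_trajectory` started in the G*C* basin
#' @param geom geometry for the projection
#' @param stop_lambda GC-basin threshold
#' @return data.frame row: time_fs, decayed, class
#' @export
classify_decay <- function(traj, geom = geometry_refs(), stop_lambda = 0.15) {
  u <- transfer_progress(traj$r1_A, traj$r2_A, geom)
  if (u[1, 1] + u[1, 2] < 1)
    stop("trajectory does not start in the G*C* basin")
  fp <- attr(traj, "first_passage_fs")
  lam <- (u[, 1] + u[, 2]) / 2
  if (is.null(fp) || !is.finite(fp)) {
    i <- which(lam < stop_lambda)
    fp <- if (length(i)) traj$t_fs[i[1]] else NA_real_
  }
  decayed <- is.finite(fp)
  cls <- "none"
  cross <- which(u[, 1] + u[, 2] <= 1)
  if (length(cross)) {
    i <- cross[1]
    landmarks <- rbind(G_minus_C_plus = c(1, 0), G_plus_C_minus = c(0, 1),
                       synchronous = c(0.5, 0.5))
    d <- sqrt((landmarks[, 1] - u[i, 1])^2 + (landmarks[, 2] - u[i, 2])^2)
    cls <- c("via G-C+", "via G+C-",
             "synchronous/near-maximum")[which.min(d)]
  }
  data.frame(time_fs = fp, decayed = decayed, class = cls,
             stringsAsFactors = FALSE)
}

#' Feature-energy trends under base-pair separation
#'
#' Fits ordinary least squares lines of the TS1, TS2, zwitterion and
#' tautomer energies (relative to GC at the same separation) against the
#' separation s, and reports the Pearson correlation of the overall
#' reaction asymmetry with s.
#'
#' @param meps list of `dpt_mep` computed at distinct separations
#' @param s_values separations (Angstrom); default taken from the MEPs
#' @return a `dpt_septrend`: list with `energies` (long data.frame),
#'   `fits` (slope, intercept, slope_se per feature), and
#'   `asymmetry_correlation`; with fewer than 3 separations the fits are
#'   refused and only the raw energies are returned
#' @export
separation_trend <- function(meps, s_values = NULL) {
  if (is.null(s_values)) s_values <- vapply(meps, function(m) m$s, 0)
  stopifnot(length(meps) == length(s_values))
  feat <- function(m) {
    E0 <- m$energy[1]
    zw_q <- .quadrant_label(m$images[, 1], m$images[, 2], geometry_refs())
    zw <- if (any(zw_q == m$via)) min(m$energy[zw_q == m$via]) - E0 else NA
    sd <- m$saddles[order(m$saddles$energy_eV), , drop = FALSE]
    lam_s <- lambda_of(m$saddles$r1, m$saddles$r2, geometry_refs())
    ts1 <- if (any(lam_s <= 0.5)) min(m$saddles$energy_eV[lam_s <= 0.5]) - E0 else NA
    ts2 <- if (any(lam_s > 0.5)) max(m$saddles$energy_eV[lam_s > 0.5]) - E0 else NA
    c(TS1 = ts1, TS2 = ts2, zwitterion = zw,
      GstarCstar = m$energy[length(m$energy)] - E0)
  }
  F <- t(vapply(meps, feat, numeric(4)))
  long <- data.frame(s_A = rep(s_values, 4),
                     feature = rep(colnames(F), each = length(s_values)),
                     energy_eV = as.vector(F))
  if (length(s_values) < 3) {
    message("fewer than 3 separations: refusing to fit; raw energies only")
    return(structure(list(energies = long, fits = NULL,
                          asymmetry_correlation = NA_real_),
                     class = "dpt_septrend"))
  }
  fits <- do.call(rbind, lapply(colnames(F), function(fn) {
    y <- F[, fn]
    if (any(!is.finite(y))) return(NULL)
    fit <- lm(y ~ s_values)
    co <- summary(fit)$coefficients
    data.frame(feature = fn, intercept = co[1, 1], slope = co[2, 1],
               slope_se = co[2, 2])
  }))
  asym <- F[, "GstarCstar"]
  corr <- if (sd(asym) > 0 && sd(s_values) > 0)
    suppressWarnings(stats::cor(asym, s_values)) else 0
  structure(list(energies = long, fits = fits,
                 asymmetry_correlation = corr),
            class = "dpt_septrend")
}

#' @export
print.dpt_profile <- function(x, ...) {
  cat(sprintf("<dpt_profile> %s (%s, T = %g K)\n", x$scenario,
              x$energy_kind, x$T))
  print(x$transitions, digits = 3)
  invisible(x)
}
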