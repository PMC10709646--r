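## Weighted-histogram analysis of umbrella-sampling trajectories.
##
## The estimator is the binless (per-frame) WHAM self-consistency: each
## frame n carries its exact 4-distance restraint energy B_j(x_n) under
## every window j, and the window free-energy constants f_j are iterated to
## self-consistency. Frames are aggregated on a fine 2D position grid
## (0.005 A) first -- mathematically identical to per-frame weights, but it
## makes each iteration a pair of small matrix-vector products.

.pos_round <- 0.005  # A, position aggregation grid for WHAM

## Precompute the WHAM ingredients from a trajectory list.
## Returns unique positions, per-position counts by window, bias matrix.
.wham_prep <- function(trajectories, windows = NULL, T = 310) {
  if (is.null(windows)) {
    windows <- lapply(trajectories, function(t) attr(t, "window"))
    if (any(vapply(windows, is.null, TRUE)))
      stop("every trajectory must carry its umbrella window (or pass `windows`)")
    windows <- unique(windows)
  }
  J <- length(windows)
  win_of <- vapply(trajectories, function(t) {
    w <- attr(t, "window")
    if (is.null(w)) return(NA_integer_)
    for (j in seq_len(J))
      if (isTRUE(all.equal(w$centers, windows[[j]]$centers)) &&
          w$k == windows[[j]]$k) return(j)
    NA_integer_
  }, 0L)
  if (any(is.na(win_of))) stop("trajectory window not found in window list")

  r1 <- unlist(lapply(trajectories, function(t) t$r1_A))
  r2 <- unlist(lapply(trajectories, function(t) t$r2_A))
  win <- rep(win_of, vapply(trajectories, nrow, 0L))
  i1 <- as.integer(round(r1 / .pos_round))
  i2 <- as.integer(round(r2 / .pos_round))
  key <- paste(i1, i2)
  uk <- !duplicated(key)
  ukey <- key[uk]
  U <- length(ukey)
  uidx <- match(key, ukey)
  ## evaluate the restraint at each cell's occupancy centroid, not its
  ## geometric centre: removes the first-order discretisation bias of the
  ## aggregation grid
  ur1 <- as.numeric(rowsum(r1, uidx)[, 1] / tabulate(uidx, U))
  ur2 <- as.numeric(rowsum(r2, uidx)[, 1] / tabulate(uidx, U))

  ## counts c[j, u]
  cnt <- matrix(0, J, U)
  tab <- table(factor(win, levels = seq_len(J)), factor(uidx, levels = seq_len(U)))
  cnt[] <- as.numeric(tab)

  ## bias energy B[j, u] = (k/2) sum_i (d_i(u) - c_ij)^2, exact 4-distance form
  geom <- geometry_refs()  # bias distances use the canonical geometry
  d <- cbind(ur1, geom$R_NN - ur1, ur2, geom$R_ON - ur2)
  B <- matrix(0, J, U)
  for (j in seq_len(J)) {
    cj <- windows[[j]]$centers
    B[j, ] <- 0.5 * windows[[j]]$k_eV *
      ((d[, 1] - cj[1])^2 + (d[, 2] - cj[2])^2 +
       (d[, 3] - cj[3])^2 + (d[, 4] - cj[4])^2)
  }
  lam_u <- lambda_of(ur1, ur2, geom)
  list(J = J, U = U, counts = cnt, B = B, lambda_u = lam_u,
       ur1 = ur1, ur2 = ur2,
       frame_uidx = uidx, frame_win = win, windows = windows,
       kT = dpt_constants$kB * T)
}

## Core self-consistent iteration. counts may be any nonnegative weights per
## (window, position). Returns w_u (unbiased weights, unnormalised) and f.
.wham_solve <- function(prep, counts, tol = 1e-6, max_iter = 100000,
                        f_init = NULL) {
  kT <- prep$kT
  Nj <- rowSums(counts)
  live <- Nj > 0
  t_u <- colSums(counts)
  E <- exp(-prep$B[live, , drop = FALSE] / kT)
  Nl <- Nj[live]
  bf <- if (is.null(f_init)) rep(0, sum(live)) else f_init[live] / kT
  for (it in seq_len(max_iter)) {
    a <- Nl * exp(bf)
    denom <- drop(a %*% E)
    w <- t_u / denom
    z <- drop(E %*% w)                 # exp(-beta f_j)
    bf_new <- -log(z)
    bf_new <- bf_new - bf_new[1]       # gauge: f_1 = 0
    delta <- max(abs(bf_new - bf))
    bf <- bf_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(paste0("WHAM convergence error: max |delta log-weight| ",
                        "%.2e after %d iterations (tol %.1e)"),
                 delta, max_iter, tol))
  f <- rep(NA_real_, prep$J); f[live] <- bf * kT
  list(w = w, f = f, iterations = it)
}

## distance from positions to the piecewise-linear transfer path
.path_distance <- function(r1, r2, path, geom) {
  lam_dense <- seq(-0.15, 1.15, length.out = 600)
  ctr <- path_window_centers(lam_dense, path = path, geom = geom)
  px <- ctr[, 1]; py <- ctr[, 3]
  d2 <- rep(Inf, length(r1))
  for (i in seq_len(length(px) - 1)) {
    ax <- px[i]; ay <- py[i]; vx <- px[i + 1] - ax; vy <- py[i + 1] - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((r1 - ax) * vx + (r2 - ay) * vy) / L2)) else 0
    d2 <- pmin(d2, (r1 - (ax + t * vx))^2 + (r2 - (ay + t * vy))^2)
  }
  sqrt(d2)
}

## Bin the unbiased weights in lambda -> min-shifted free energy profile.
## `in_tube` optionally restricts binning to the pathway tube so that the
## profile is the free energy of the chosen transfer pathway (the lambda
## level sets are degenerate between pathways). Positions visited fewer
## than `min_visits` times are excluded from the profile (not from the
## self-consistency): a frame far outside every window's coverage carries
## an unbounded importance ratio and a single lucky visit would otherwise
## dominate its bin.
.wham_bin <- function(prep, w, counts, bins, lambda_range, in_tube = NULL,
                      min_visits = 3) {
  br <- seq(lambda_range[1], lambda_range[2], length.out = bins + 1)
  mid <- (br[-1] + br[-length(br)]) / 2
  bin_u <- findInterval(prep$lambda_u, br, rightmost.closed = TRUE)
  ok <- bin_u >= 1 & bin_u <= bins & colSums(counts) >= min_visits
  if (!is.null(in_tube)) ok <- ok & in_tube
  Wb <- vapply(seq_len(bins), function(b) sum(w[ok & bin_u == b]), 0)
  nb <- vapply(seq_len(bins), function(b)
    sum(colSums(counts)[ok & bin_u == b]), 0)
  G <- ifelse(Wb > 0, -prep$kT * log(Wb), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  data.frame(lambda = mid, G_eV = G, n = nb)
}

#' Potential of mean force over lambda by WHAM
#'
#' Combines umbrella-sampling trajectories into an unbiased free-energy
#' profile over the collective coordinate lambda. The restraint energy of
#' every frame is evaluated exactly from its four stored hydrogen-bond
#' distances under every window; the window free-energy constants are then
#' iterated to self-consistency until the largest change in the unitless
#' log-weight falls below `tol`.
#'
#' @param trajectories list of `dpt_trajectory` from [run_umbrella_series()]
#' @param bins number of lambda bins
#' @param lambda_range binning range
#' @param tol self-consistency tolerance on the log-weights
#' @param max_iter iteration cap (error on non-convergence)
#' @param T temperature, K
#' @param path pathway whose profile is reported ("asynchronous",
#'   "synchronous", or "none"): because the lambda level sets are shared
#'   between pathways, the profile is binned from positions within `tube`
#'   Angstrom of the pathway (the paper-style per-pathway PMF); "none"
#'   bins every frame
#' @param tube pathway tube half-width, Angstrom
#' @return a `dpt_pmf`: data.frame (lambda, G_eV, sigma_eV, n) min-shifted
#'   to zero, bins never sampled left NA; WHAM metadata in attributes
#' @export
wham_pmf <- function(trajectories, bins = 120, lambda_range = c(-0.1, 1.1),
                     tol = 1e-6, max_iter = 100000, T = 310,
                     path = c("asynchronous", "synchronous", "none"),
                     tube = 0.35) {
  path <- match.arg(path)
  prep <- .wham_prep(trajectories, T = T)
  in_tube <- if (path == "none") NULL else
    .path_distance(prep$ur1, prep$ur2, path, geometry_refs()) <= tube
  sol <- .wham_solve(prep, prep$counts, tol = tol, max_iter = max_iter)
  prof <- .wham_bin(prep, sol$w, prep$counts, bins, lambda_range, in_tube)
  prof$sigma_eV <- NA_real_
  prof <- prof[, c("lambda", "G_eV", "sigma_eV", "n")]
  structure(prof, class = c("dpt_pmf", "data.frame"),
            T = T, f = sol$f, iterations = sol$iterations,
            windows = prep$windows,
            total_frames = sum(prep$counts),
            bins = bins, lambda_range = lambda_range, tol = tol)
}

#' Block-bootstrap ensemble of WHAM profiles
#'
#' Resamples, within every trajectory, blocks of consecutive frames (block
#' length chosen to exceed the velocity autocorrelation time) and re-solves
#' WHAM for each resample. The central profile gains per-bin bootstrap
#' standard deviations.
#'
#' @param trajectories list of `dpt_trajectory`
#' @param n_boot number of bootstrap samples (the conventional 100)
#' @param seed RNG seed for the resampling
#' @param block_fs block length in fs
#' @param ... passed to [wham_pmf()] (bins, tol, T, ...)
#' @return list with elements `pmf` (central profile with sigma filled),
#'   `replicates` (list of bootstrap `dpt_pmf`s) and `n_boot`
#' @export
bootstrap_pmfs <- function(trajectories, n_boot = 100, seed = 1L,
                           block_fs = 50, bins = 120,
                           lambda_range = c(-0.1, 1.1), tol = 1e-6,
                           max_iter = 100000, T = 310,
                           path = c("asynchronous", "synchronous", "none"),
                           tube = 0.35) {
  stopifnot(n_boot >= 1)
  path <- match.arg(path)
  prep <- .wham_prep(trajectories, T = T)
  in_tube <- if (path == "none") NULL else
    .path_distance(prep$ur1, prep$ur2, path, geometry_refs()) <= tube
  sol <- .wham_solve(prep, prep$counts, tol = tol, max_iter = max_iter)
  central <- .wham_bin(prep, sol$w, prep$counts, bins, lambda_range, in_tube)

  ## per-trajectory frame index ranges and block structure
  nper <- vapply(trajectories, nrow, 0L)
  offs <- cumsum(c(0L, nper[-length(nper)]))
  dt_frame <- vapply(trajectories, function(t)
    if (nrow(t) > 1) t$t_fs[2] - t$t_fs[1] else 1, 0)
  set.seed(seed)
  reps <- vector("list", n_boot)
  for (bset in seq_len(n_boot)) {
    cnt <- matrix(0, prep$J, prep$U)
    for (ti in seq_along(trajectories)) {
      n <- nper[ti]
      bl <- max(1L, round(block_fs / dt_frame[ti]))
      nblocks <- ceiling(n / bl)
      starts <- sample.int(max(1L, n - bl + 1L), nblocks, replace = TRUE)
      idx <- unlist(lapply(starts, function(s) s:(s + bl - 1L)))[seq_len(n)]
      u <- prep$frame_uidx[offs[ti] + idx]
      j <- prep$frame_win[offs[ti] + 1L]
      tb <- tabulate(u, nbins = prep$U)
      cnt[j, ] <- cnt[j, ] + tb
    }
    bsol <- .wham_solve(prep, cnt, tol = tol, max_iter = max_iter,
                        f_init = sol$f)
    reps[[bset]] <- .wham_bin(prep, bsol$w, cnt, bins, lambda_range, in_tube)
  }
  Gm <- vapply(reps, function(r) r$G_eV, numeric(bins))
  sig <- apply(Gm, 1, function(x) if (sum(is.finite(x)) > 1) sd(x, na.rm = TRUE) else 0)
  if (n_boot == 1) {
    sig[] <- 0
    warning("n_boot = 1: bootstrap standard deviation is 0 by convention (degenerate)")
  }
  pmf <- central
  pmf$sigma_eV <- sig
  pmf <- pmf[, c("lambda", "G_eV", "sigma_eV", "n")]
  pmf <- structure(pmf, class = c("dpt_pmf", "data.frame"),
                   T = T, f = sol$f, iterations = sol$iterations,
                   windows = prep$windows, total_frames = sum(prep$counts),
                   bins = bins, lambda_range = lambda_range, tol = tol,
                   n_boot = n_boot, block_fs = block_fs, seed = seed)
  list(pmf = pmf, replicates = reps, n_boot = n_boot)
}

#' Exact Boltzmann marginal over lambda (quadrature reference)
#'
#' Integrates the 2D Boltzmann density of a model surface over a tube
#' around the sampled transfer path and bins it in lambda: the analytic
#' counterpart of the umbrella-sampling + WHAM estimate, used to validate
#' the estimator.
#'
#' @param params calibrated `dpt_surface`
#' @param path "asynchronous" or "synchronous" window path
#' @param tube half-width of the integration tube around the path, Angstrom
#' @param bins,lambda_range lambda binning (match the WHAM settings)
#' @param T temperature, K
#' @param h quadrature grid spacing, Angstrom
#' @param s base-pair separation
#' @return data.frame (lambda, G_eV) min-shifted, NA outside the tube
#' @export
boltzmann_marginal <- function(params, path = c("asynchronous", "synchronous"),
                               tube = 0.35, bins = 120,
                               lambda_range = c(-0.1, 1.1), T = 310,
                               h = 0.005, s = 0) {
  path <- match.arg(path)
  geom <- params$geom
  g <- seq(geom$domain[1], geom$domain[2], by = h)
  gr <- expand.grid(r1 = g, r2 = g)
  ## distance to the window-center path (piecewise linear in (r1, r2))
  lam_dense <- seq(lambda_range[1], lambda_range[2], length.out = 600)
  ctr <- path_window_centers(lam_dense, path = path, geom = geom)
  px <- ctr[, 1]; py <- ctr[, 3]
  d2 <- rep(Inf, nrow(gr))
  for (i in seq_len(length(px) - 1)) {
    ax <- px[i]; ay <- py[i]; bx <- px[i + 1]; by <- py[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((gr$r1 - ax) * vx + (gr$r2 - ay) * vy) / L2)) else 0
    dd <- (gr$r1 - (ax + t * vx))^2 + (gr$r2 - (ay + t * vy))^2
    d2 <- pmin(d2, dd)
  }
  keep <- d2 <= tube^2
  kT <- dpt_constants$kB * T
  E <- surface_evaluate(params, gr$r1[keep], gr$r2[keep], s = s, check = FALSE)
  lam <- lambda_of(gr$r1[keep], gr$r2[keep], geom)
  br <- seq(lambda_range[1], lambda_range[2], length.out = bins + 1)
  mid <- (br[-1] + br[-length(br)]) / 2
  b <- findInterval(lam, br, rightmost.closed = TRUE)
  ok <- b >= 1 & b <= bins
  Z <- vapply(seq_len(bins), function(k) sum(exp(-E[ok & b == k] / kT)), 0)
  G <- ifelse(Z > 0, -kT * log(Z * h * h), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  data.frame(lambda = mid, G_eV = G)
}

#' Sampling-time convergence diagnostic for WHAM profiles
#'
#' Computes the RMS difference of each profile in a series (increasing
#' sampling time) to the longest-time profile and fits a four-parameter
#' logistic in log-time. The series is converged when the final RMS is
#' below `threshold` and the logistic has plateaued (derivative at the
#' final time below 10% of its maximum).
#'
#' @param pmf_series list of `dpt_pmf` at increasing sampling times
#' @param times sampling times (any monotone unit); default: total frames
#' @param threshold RMS convergence threshold, eV
#' @return list: data.frame `rms` (time, rms_eV), `fit` (logistic
#'   parameters or NULL), `converged`, `plateau`
#' @export
convergence_check <- function(pmf_series, times = NULL, threshold = 0.01) {
  stopifnot(length(pmf_series) >= 4)
  if (is.null(times))
    times <- vapply(pmf_series, function(p)
      as.numeric(attr(p, "total_frames")), 0)
  stopifnot(!is.unsorted(times))
  ref <- pmf_series[[length(pmf_series)]]
  rms <- vapply(pmf_series, function(p) {
    ok <- is.finite(p$G_eV) & is.finite(ref$G_eV)
    sqrt(mean((p$G_eV[ok] - ref$G_eV[ok])^2))
  }, 0)
  df <- data.frame(time = times, rms_eV = rms)
  ## last point is identically zero by construction; fit on the rest too,
  ## a decaying logistic in log-time: A + (B - A) / (1 + (t/t0)^p)
  fit <- tryCatch({
    lt <- log(times)
    f <- minpack.lm::nlsLM(
      rms_eV ~ A + (B - A) / (1 + exp((log(time) - m) / w)),
      data = df,
      start = list(A = min(rms), B = max(rms), m = mean(lt),
                   w = diff(range(lt)) / 6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    f
  }, error = function(e) NULL)
  plateau <- NA
  if (!is.null(fit)) {
    cf <- coef(fit)
    dlogis <- function(l) {
      z <- exp((l - cf["m"]) / cf["w"])
      abs((cf["B"] - cf["A"]) * z / (cf["w"] * (1 + z)^2))
    }
    lgrid <- seq(min(log(times)), max(log(times)), length.out = 200)
    dmax <- max(dlogis(lgrid))
    plateau <- dlogis(max(log(times))) < 0.1 * dmax
  }
  final_rms <- if (length(rms) >= 2) rms[length(rms) - 1] else rms[1]
  converged <- final_rms < threshold && (is.na(plateau) || plateau)
  if (is.null(fit))
    message("logistic fit failed; using threshold-only convergence criterion")
  list(rms = df, fit = fit, converged = converged, plateau = plateau,
       final_rms = final_rms, threshold = threshold)
}

#' @export
print.dpt_pmf <- function(x, ...) {
  ok <- is.finite(x$G_eV)
  cat(sprintf("<dpt_pmf> %d/%d bins sampled, %d frames, %d WHAM iterations\n",
              sum(ok), nrow(x), attr(x, "total_frames"),
              attr(x, "iterations")))
  cat(sprintf("  max G %.3f eV at lambda %.2f; T = %g K\n",
              max(x$G_eV[ok]), x$lambda[ok][which.max(x$G_eV[ok])],
              attr(x, "T")))
  invisible(x)
}
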