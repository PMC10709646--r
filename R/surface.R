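## Analytic 2D model potentials over the two proton coordinates.
##
## The model stands in for the instantaneous QM/MM energy landscape of the
## double proton transfer: a quadratic confinement background carries a sum
## of Gaussian terms --
##   * one isotropic well per chemical state that exists in a scenario
##     (GC always; the zwitterions and the tautomer when the scenario's
##     stationary table lists them),
##   * one broad "ramp" per non-reference minimum whose amplitude sets that
##     state's energy relative to GC (these model the environmental
##     destabilisation of the rare protonation states),
##   * one bump per transition state whose signed amplitude sets the saddle
##     energy,
##   * separation-coupling bumps over the transition/zwitterion regions,
##     scaled linearly by the base-pair separation s.
## Widths are fixed shape constants chosen so that (i) a 33x33 grid resolves
## the surface to well below the smallest printed barrier differences and
## (ii) the negative curvature along the transfer path stays below the
## combined umbrella restraint stiffness, so that a window ladder can
## actually cover the path (see the methods vignette).

## Thermal (umbrella-sampled) surfaces use soft, broad features so the
## negative curvature along the transfer path stays comparable to the
## umbrella restraint stiffness; frozen (instantaneous) surfaces carry the
## sharper, higher barriers of the snapshot landscapes and are only probed
## by grid/NEB/decay operations, so they use stiffer wells.
.surface_shape_defaults <- list(
  well_width   = 0.38,   # A, isotropic state wells
  well_depth   = 1.20,   # eV, non-reference state wells
  gc_depth     = 1.60,   # eV, GC reference well
  ramp_width   = 0.65,   # A, broad per-state energy ramps
  bump_width   = 0.30,   # A, transition-state bumps
  conf_c0      = 0.30,   # eV/A^2, quadratic confinement stiffness
  sep_width    = 0.30,   # A, separation-coupling bumps
  sep_amp_ts   = 0.80,   # eV/A at TS1 and TS2
  sep_amp_zw   = 0.60,   # eV/A at the G-C+ zwitterion
  ## central repulsion: moving both protons at once costs extra energy, so
  ## the synchronous diagonal lies above the asynchronous corner routes
  ## (the ordering of the two pathways reported from umbrella sampling)
  sync_amp = 0.8, sync_width = 0.28
)
.surface_shape_frozen <- modifyList(.surface_shape_defaults, list(
  well_width = 0.33, well_depth = 2.0, gc_depth = 2.2,
  ramp_width = 0.60, bump_width = 0.25,
  conf_c0 = 0.60,
  ## fixed central repulsion: the cost of having both protons mid-flight
  ## (synchronous ridge); keeps detours around the fitted saddles closed
  sync_amp = 1.2, sync_width = 0.40
))

## Compression walls: a proton within ~0.9 A of its acceptor (high side)
## or squeezed into its donor (low side) is strongly repelled. Cubic
## hinges (C2 smooth, zero fourth derivative) so grid interpolation stays
## accurate.
.wall_amp <- 60      # eV/A^3, acceptor side
.wall_margin <- 0.93 # A: wall onset at r = R_donor_acceptor - margin
.wall_lo_amp <- 200  # eV/A^3, donor side
.wall_lo_on <- 0.985 # A: donor-side onset

#' Default shape constants for the model surfaces
#'
#' @param kind "thermal" for umbrella-sampled free-energy surfaces,
#'   "frozen" for instantaneous potential-energy surfaces
#' @return named list of shape constants
#' @export
surface_shape <- function(kind = c("thermal", "frozen")) {
  kind <- match.arg(kind)
  if (kind == "frozen") .surface_shape_frozen else .surface_shape_defaults
}

#' Reference positions of the chemical states in the proton-coordinate plane
#'
#' GC has both protons at the covalent distance; a transferred proton sits
#' at (donor-acceptor length - covalent distance). TS1/TS2 are the midpoints
#' of the two legs of the asynchronous path via G-C+, SYNC_TS the centre of
#' the plane.
#'
#' @param geom a [geometry_refs()] object
#' @return named list of c(r1, r2) positions, Angstrom
#' @export
state_positions <- function(geom = geometry_refs()) {
  a0 <- geom$r_cov; a1 <- geom$R_NN - geom$r_cov
  b0 <- geom$r_cov; b1 <- geom$R_ON - geom$r_cov
  list(
    GC             = c(a0, b0),
    G_minus_C_plus = c(a1, b0),
    G_plus_C_minus = c(a0, b1),
    GstarCstar     = c(a1, b1),
    TS1            = c((a0 + a1) / 2, b0),
    TS2            = c(a1, (b0 + b1) / 2),
    SYNC_TS        = c((a0 + a1) / 2, (b0 + b1) / 2)
  )
}

#' Construct model surface parameters
#'
#' Builds an uncalibrated surface: state wells at the positions of
#' [state_positions()], zero-amplitude ramps/bumps for the requested states,
#' quadratic confinement, and the default separation coupling. Amplitudes
#' are normally set by [calibrate_surface()].
#'
#' @param states minima present on the surface (GC is always included)
#' @param saddles transition states carrying a tunable bump
#' @param geom a [geometry_refs()] object
#' @param shape named list overriding entries of the shape defaults
#'   (well/ramp/bump widths, depths, confinement stiffness, separation
#'   coupling amplitudes)
#' @param scenario optional scenario id stored in the object
#' @return an object of class `dpt_surface`
#' @export
surface_params <- function(states = c("G_minus_C_plus", "GstarCstar"),
                           saddles = c("TS1", "TS2"),
                           geom = geometry_refs(),
                           shape = list(),
                           scenario = "custom",
                           kind = c("thermal", "frozen")) {
  kind <- match.arg(kind)
  sh <- modifyList(surface_shape(kind), shape)
  pos <- state_positions(geom)
  states <- union("GC", states)
  stopifnot(all(states %in% names(pos)), all(saddles %in% names(pos)))
  wells <- data.frame(
    state = states,
    x = vapply(states, function(s) pos[[s]][1], 0),
    y = vapply(states, function(s) pos[[s]][2], 0),
    depth = ifelse(states == "GC", sh$gc_depth, sh$well_depth),
    w = sh$well_width, stringsAsFactors = FALSE)
  rstates <- setdiff(states, "GC")
  ramps <- data.frame(
    state = rstates,
    x = vapply(rstates, function(s) pos[[s]][1], 0),
    y = vapply(rstates, function(s) pos[[s]][2], 0),
    amp = numeric(length(rstates)),
    w = rep(sh$ramp_width, length(rstates)), stringsAsFactors = FALSE)
  bumps <- data.frame(
    state = saddles,
    x = vapply(saddles, function(s) pos[[s]][1], 0),
    y = vapply(saddles, function(s) pos[[s]][2], 0),
    amp = numeric(length(saddles)),
    w = rep(sh$bump_width, length(saddles)), stringsAsFactors = FALSE)
  if (!is.null(sh$sync_amp) && sh$sync_amp > 0)
    bumps <- rbind(bumps, data.frame(
      state = "SYNC_BG", x = pos$SYNC_TS[1], y = pos$SYNC_TS[2],
      amp = sh$sync_amp, w = sh$sync_width, stringsAsFactors = FALSE))
  ## a zwitterion absent from a frozen scenario has no stable basin: a
  ## broad repulsion centred beyond its corner tilts the whole corner
  ## region outward so the stiff frozen-kind confinement cannot carve a
  ## pocket there. Thermal surfaces (softer walls) form no such pockets
  ## and stay untouched, as do bare single-well test surfaces.
  excl <- if (kind == "frozen" && length(setdiff(states, "GC")))
    setdiff(c("G_minus_C_plus", "G_plus_C_minus"), states) else character(0)
  for (zw in excl) {
    ctr0 <- mean(geom$domain)
    bumps <- rbind(bumps, data.frame(
      state = paste0("EXCL_", zw),
      x = pos[[zw]][1] + 0.6 * (pos[[zw]][1] - ctr0),
      y = pos[[zw]][2] + 0.6 * (pos[[zw]][2] - ctr0),
      amp = 1.2, w = 0.42, stringsAsFactors = FALSE))
  }
  sep_states <- intersect(c("TS1", "TS2", "G_minus_C_plus"),
                          c(saddles, states))
  sep <- data.frame(
    state = sep_states,
    x = vapply(sep_states, function(s) pos[[s]][1], 0),
    y = vapply(sep_states, function(s) pos[[s]][2], 0),
    amp = ifelse(sep_states == "G_minus_C_plus", sh$sep_amp_zw, sh$sep_amp_ts),
    w = rep(sh$sep_width, length(sep_states)), stringsAsFactors = FALSE)
  ctr <- mean(geom$domain)
  p <- list(scenario = scenario, geom = geom, shape = sh,
            wells = wells, ramps = ramps, bumps = bumps, sep = sep,
            conf = c(c0 = sh$conf_c0, xc = ctr, yc = ctr),
            offset = 0, calibration = NULL)
  class(p) <- "dpt_surface"
  p
}

## Compile the Gaussian terms to a matrix (x, y, amp, w); separation terms
## are kept separate and scaled by s at evaluation time.
surface_terms <- function(params) {
  g <- rbind(
    cbind(params$wells$x, params$wells$y, -params$wells$depth, params$wells$w),
    if (nrow(params$ramps)) cbind(params$ramps$x, params$ramps$y,
                                  params$ramps$amp, params$ramps$w),
    if (nrow(params$bumps)) cbind(params$bumps$x, params$bumps$y,
                                  params$bumps$amp, params$bumps$w))
  s <- if (nrow(params$sep))
    cbind(params$sep$x, params$sep$y, params$sep$amp, params$sep$w)
  else matrix(0, 0, 4)
  colnames(g) <- colnames(s) <- c("x", "y", "amp", "w")
  list(gauss = g, sep = s, conf = params$conf, offset = params$offset,
       wall = c(amp = .wall_amp,
                x_on = params$geom$R_NN - .wall_margin,
                y_on = params$geom$R_ON - .wall_margin,
                lo_amp = .wall_lo_amp, lo_on = .wall_lo_on))
}

.eval_terms <- function(tm, r1, r2, s) {
  e <- tm$offset +
    tm$conf[["c0"]] * ((r1 - tm$conf[["xc"]])^2 + (r2 - tm$conf[["yc"]])^2) +
    tm$wall[["amp"]] * (pmax(0, r1 - tm$wall[["x_on"]])^3 +
                        pmax(0, r2 - tm$wall[["y_on"]])^3) +
    tm$wall[["lo_amp"]] * (pmax(0, tm$wall[["lo_on"]] - r1)^3 +
                           pmax(0, tm$wall[["lo_on"]] - r2)^3)
  g <- tm$gauss
  for (i in seq_len(nrow(g)))
    e <- e + g[i, "amp"] *
      exp(-((r1 - g[i, "x"])^2 + (r2 - g[i, "y"])^2) / (2 * g[i, "w"]^2))
  if (s != 0) {
    sp <- tm$sep
    for (i in seq_len(nrow(sp)))
      e <- e + s * sp[i, "amp"] *
        exp(-((r1 - sp[i, "x"])^2 + (r2 - sp[i, "y"])^2) / (2 * sp[i, "w"]^2))
  }
  e
}

.grad_terms <- function(tm, r1, r2, s) {
  g1 <- 2 * tm$conf[["c0"]] * (r1 - tm$conf[["xc"]]) +
    3 * tm$wall[["amp"]] * pmax(0, r1 - tm$wall[["x_on"]])^2 -
    3 * tm$wall[["lo_amp"]] * pmax(0, tm$wall[["lo_on"]] - r1)^2
  g2 <- 2 * tm$conf[["c0"]] * (r2 - tm$conf[["yc"]]) +
    3 * tm$wall[["amp"]] * pmax(0, r2 - tm$wall[["y_on"]])^2 -
    3 * tm$wall[["lo_amp"]] * pmax(0, tm$wall[["lo_on"]] - r2)^2
  rows <- rbind(tm$gauss,
                if (s != 0 && nrow(tm$sep))
                  cbind(tm$sep[, 1:2, drop = FALSE],
                        s * tm$sep[, 3], tm$sep[, 4, drop = FALSE]))
  for (i in seq_len(nrow(rows))) {
    dx <- r1 - rows[i, 1]; dy <- r2 - rows[i, 2]; w2 <- rows[i, 4]^2
    e <- rows[i, 3] * exp(-(dx^2 + dy^2) / (2 * w2))
    g1 <- g1 - e * dx / w2
    g2 <- g2 - e * dy / w2
  }
  cbind(g1, g2)
}

.hess_terms <- function(tm, r1, r2, s) {
  h11 <- 2 * tm$conf[["c0"]] +
    6 * tm$wall[["amp"]] * pmax(0, r1 - tm$wall[["x_on"]]) +
    6 * tm$wall[["lo_amp"]] * pmax(0, tm$wall[["lo_on"]] - r1)
  h22 <- 2 * tm$conf[["c0"]] +
    6 * tm$wall[["amp"]] * pmax(0, r2 - tm$wall[["y_on"]]) +
    6 * tm$wall[["lo_amp"]] * pmax(0, tm$wall[["lo_on"]] - r2)
  h12 <- 0
  rows <- rbind(tm$gauss,
                if (s != 0 && nrow(tm$sep))
                  cbind(tm$sep[, 1:2, drop = FALSE],
                        s * tm$sep[, 3], tm$sep[, 4, drop = FALSE]))
  for (i in seq_len(nrow(rows))) {
    dx <- r1 - rows[i, 1]; dy <- r2 - rows[i, 2]; w2 <- rows[i, 4]^2
    e <- rows[i, 3] * exp(-(dx^2 + dy^2) / (2 * w2))
    h11 <- h11 + e * (dx^2 / w2 - 1) / w2
    h22 <- h22 + e * (dy^2 / w2 - 1) / w2
    h12 <- h12 + e * dx * dy / w2^2
  }
  matrix(c(h11, h12, h12, h22), 2, 2)
}

#' Evaluate the model surface
#'
#' @param params a `dpt_surface` object
#' @param r1,r2 proton coordinates, Angstrom (equal-length vectors)
#' @param s base-pair separation, Angstrom (scalar, >= 0)
#' @param check check the coordinate domain (disable for speed in inner loops)
#' @return energy in eV (vector)
#' @export
surface_evaluate <- function(params, r1, r2, s = 0, check = TRUE) {
  stopifnot(inherits(params, "dpt_surface"), length(s) == 1, s >= 0)
  if (check) check_domain(r1, r2, params$geom)
  .eval_terms(surface_terms(params), r1, r2, s)
}

#' Analytic gradient of the model surface
#'
#' Matches central finite differences of [surface_evaluate()] to relative
#' error below 1e-4 (exercised in the test suite).
#'
#' @inheritParams surface_evaluate
#' @return a two-column matrix (dE/dr1, dE/dr2), eV/Angstrom
#' @export
surface_gradient <- function(params, r1, r2, s = 0, check = TRUE) {
  stopifnot(inherits(params, "dpt_surface"), length(s) == 1, s >= 0)
  if (check) check_domain(r1, r2, params$geom)
  .grad_terms(surface_terms(params), r1, r2, s)
}

#' Analytic Hessian of the model surface at a point
#'
#' @inheritParams surface_evaluate
#' @return 2x2 Hessian matrix, eV/Angstrom^2
#' @export
surface_hessian <- function(params, r1, r2, s = 0) {
  stopifnot(length(r1) == 1, length(r2) == 1)
  .hess_terms(surface_terms(params), r1, r2, s)
}

#' A callable surface interface
#'
#' Normalises a surface-like object to a list with elements `f(r1, r2)`
#' (energy, vectorised), `g(r1, r2)` (gradient row per point) and `domain`.
#' Methods exist for `dpt_surface` (analytic, at fixed separation s) and
#' for grid interpolants (`dpt_interp`, see [interpolate_grid()]).
#'
#' @param x surface-like object
#' @param s base-pair separation for analytic surfaces
#' @return list(f, g, domain)
#' @export
as_surface_fun <- function(x, s = 0) UseMethod("as_surface_fun")

#' @export
as_surface_fun.dpt_surface <- function(x, s = 0) {
  tm <- surface_terms(x)
  list(f = function(r1, r2) .eval_terms(tm, r1, r2, s),
       g = function(r1, r2) .grad_terms(tm, r1, r2, s),
       domain = x$geom$domain)
}

## ---- stationary-point machinery ------------------------------------------

.stationary_grad_tol <- 1e-4  # eV/A: definition of "stationary"

## quasi-Newton descent to a local minimum from a start point. A damped
## steepest-descent pre-phase (steps capped at 0.02 A) keeps the search in
## the basin of the start even when neighbouring barriers are shallow;
## BFGS then converges the remaining gradient.
find_min_2d <- function(sf, start) {
  p <- start
  for (i in 1:300) {
    g <- drop(sf$g(p[1], p[2])); gn <- sqrt(sum(g^2))
    if (gn < 0.05) break
    p <- p - g * min(0.02 / gn, 0.5)
  }
  res <- optim(p, fn = function(p) sf$f(p[1], p[2]),
               gr = function(p) drop(sf$g(p[1], p[2])),
               method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  gn <- sqrt(sum(sf$g(res$par[1], res$par[2])^2))
  list(pos = res$par, energy = res$value, grad_norm = gn,
       converged = gn < .stationary_grad_tol)
}

## Eigenvector-following search for an index-1 saddle: at each step move
## uphill along the lowest Hessian mode and downhill along the other
## (coincides with Newton once the Hessian has signature (+,-)).
find_saddle_2d <- function(params, start, s = 0, maxit = 300) {
  tm <- surface_terms(params)
  p <- start
  for (i in seq_len(maxit)) {
    g <- drop(.grad_terms(tm, p[1], p[2], s))
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- .hess_terms(tm, p[1], p[2], s)
    e <- eigen(H, symmetric = TRUE)          # values in decreasing order
    gl <- drop(t(e$vectors) %*% g)
    step <- (-gl[1] / max(abs(e$values[1]), 0.3)) * e$vectors[, 1] +
            ( gl[2] / max(abs(e$values[2]), 0.3)) * e$vectors[, 2]
    n <- sqrt(sum(step^2))
    if (n > 0.05) step <- step * 0.05 / n    # trust region
    p <- p + step
  }
  g <- drop(.grad_terms(tm, p[1], p[2], s))
  if (sqrt(sum(g^2)) > 1e-6) {
    ## Newton stalled (e.g. near-singular Hessian): minimise |grad|^2,
    ## whose gradient is H g, from the current iterate
    res <- optim(p, fn = function(q) sum(.grad_terms(tm, q[1], q[2], s)^2),
                 gr = function(q) {
                   gq <- drop(.grad_terms(tm, q[1], q[2], s))
                   drop(2 * .hess_terms(tm, q[1], q[2], s) %*% gq)
                 },
                 method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 500))
    p <- res$par
    g <- drop(.grad_terms(tm, p[1], p[2], s))
  }
  H <- .hess_terms(tm, p[1], p[2], s)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  list(pos = p, energy = .eval_terms(tm, p[1], p[2], s),
       grad_norm = sqrt(sum(g^2)), n_negative = sum(ev < 0),
       converged = sqrt(sum(g^2)) < .stationary_grad_tol)
}

## Seed a saddle search: dynamic-programming minimax over monotone grid
## paths between two minima gives the bottleneck of the best path; the
## highest point of that path is a reliable Newton start for the saddle.
.saddle_seed <- function(tm, s, from, to, n = 61, pad = 0.15, domain) {
  lo <- pmax(pmin(from, to) - pad, domain[1])
  hi <- pmin(pmax(from, to) + pad, domain[2])
  xs <- seq(lo[1], hi[1], length.out = n)
  ys <- seq(lo[2], hi[2], length.out = n)
  ## orient axes so 'to' is up-right of 'from'
  fx <- to[1] < from[1]; fy <- to[2] < from[2]
  if (fx) xs <- rev(xs)
  if (fy) ys <- rev(ys)
  E <- outer(xs, ys, function(a, b) .eval_terms(tm, a, b, s))
  i0 <- which.min(abs(xs - from[1])); j0 <- which.min(abs(ys - from[2]))
  i1 <- which.min(abs(xs - to[1]));   j1 <- which.min(abs(ys - to[2]))
  if (i1 < i0 || j1 < j0) return(NULL)
  V <- matrix(Inf, n, n)
  V[i0, j0] <- E[i0, j0]
  for (i in i0:i1) for (j in j0:j1) {
    if (i == i0 && j == j0) next
    prev <- min(if (i > i0) V[i - 1, j] else Inf,
                if (j > j0) V[i, j - 1] else Inf)
    V[i, j] <- max(E[i, j], prev)
  }
  ## backtrack the optimal path and take its highest node
  i <- i1; j <- j1; peak <- c(xs[i], ys[j]); emax <- E[i, j]
  while (i > i0 || j > j0) {
    if (i > i0 && (j == j0 || V[i - 1, j] <= V[i, j - 1])) i <- i - 1
    else j <- j - 1
    if (E[i, j] > emax) { emax <- E[i, j]; peak <- c(xs[i], ys[j]) }
  }
  peak
}

#' Locate the stationary points of a calibrated surface
#'
#' Minima are found by quasi-Newton descent started at the state well
#' centres, saddles by a damped Newton search started at the bump centres.
#' Energies are reported relative to the GC minimum.
#'
#' @param params a `dpt_surface`
#' @param states which states to locate (default: all wells and bumps of
#'   the surface)
#' @param s base-pair separation, Angstrom
#' @param relative report energies relative to the GC minimum
#' @return data.frame (state, r1, r2, energy_eV, grad_norm, index) where
#'   index is the number of negative Hessian eigenvalues (0 = minimum,
#'   1 = saddle)
#' @export
stationary_energies <- function(params, states = NULL, s = 0,
                                relative = TRUE) {
  sf <- as_surface_fun(params, s = s)
  min_states <- params$wells$state
  sad_states <- setdiff(params$bumps$state,
                        grep("^(SYNC_BG|EXCL_)", params$bumps$state,
                             value = TRUE))
  if (!is.null(states)) {
    min_states <- intersect(min_states, states)
    sad_states <- intersect(sad_states, states)
    min_states <- union(if (relative) "GC", min_states)
  }
  rows <- list()
  for (st in min_states) {
    start <- unlist(params$wells[params$wells$state == st, c("x", "y")])
    m <- find_min_2d(sf, start)
    H <- surface_hessian(params, m$pos[1], m$pos[2], s)
    rows[[st]] <- data.frame(state = st, r1 = m$pos[1], r2 = m$pos[2],
                             energy_eV = m$energy, grad_norm = m$grad_norm,
                             index = sum(eigen(H, TRUE, TRUE)$values < 0))
  }
  tm <- surface_terms(params)
  sep_pair <- list(TS1 = c("GC", "G_minus_C_plus"),
                   TS2 = c("G_minus_C_plus", "GstarCstar"),
                   SYNC_TS = c("GC", "GstarCstar"))
  for (st in sad_states) {
    start <- unlist(params$bumps[params$bumps$state == st, c("x", "y")])
    pair <- sep_pair[[st]]
    if (!is.null(pair) && all(pair %in% names(rows))) {
      seed <- .saddle_seed(tm, s,
                           from = c(rows[[pair[1]]]$r1, rows[[pair[1]]]$r2),
                           to   = c(rows[[pair[2]]]$r1, rows[[pair[2]]]$r2),
                           domain = params$geom$domain)
      if (!is.null(seed)) start <- seed
    }
    sdl <- find_saddle_2d(params, start, s = s)
    rows[[st]] <- data.frame(state = st, r1 = sdl$pos[1], r2 = sdl$pos[2],
                             energy_eV = sdl$energy, grad_norm = sdl$grad_norm,
                             index = sdl$n_negative)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (relative) {
    if (!"GC" %in% out$state) stop("GC minimum required for relative energies")
    out$energy_eV <- out$energy_eV - out$energy_eV[out$state == "GC"]
  }
  out
}

## ---- calibration ----------------------------------------------------------

#' Load a packaged stationary-point calibration table
#'
#' The package ships transcribed stationary-point energies (eV, relative to
#' canonical GC) for seven scenarios: `duplex_thermal`,
#' `helicaseN1_thermal`, `helicaseN_thermal`, `n624a_thermal` (umbrella
#' sampling free energies) and `duplex_frozen`, `helicaseN_frozen`,
#' `n624a_frozen` (frozen-surface minimum-energy-path energies).
#'
#' @param scenario scenario id, or NULL for the full table
#' @param file optional path to an external table with columns
#'   scenario,state,energy_eV,tolerance_eV
#' @return data.frame (scenario, state, energy_eV, tolerance_eV)
#' @export
stationary_table <- function(scenario = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "stationary_tables.csv", package = "gcdpt")
  if (!nzchar(file) || !file.exists(file))
    stop("configuration error: calibration table file not found: ",
         if (is.null(file)) "(packaged)" else file)
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("scenario", "state", "energy_eV", "tolerance_eV")
  if (!all(need %in% names(tab)))
    stop("calibration table must have columns ", paste(need, collapse = ","))
  if (!is.null(scenario)) {
    tab <- tab[tab$scenario == scenario, ]
    if (!nrow(tab)) stop("unknown scenario: ", scenario)
  }
  tab
}

#' Calibrate a model surface against a stationary-point table
#'
#' Adjusts the per-state ramp amplitudes and transition-state bump
#' amplitudes by derivative-free least squares (Nelder-Mead, iteration cap
#' `maxit`) so that every stationary-point energy of the surface -- located
#' by quasi-Newton/Newton searches at each step -- matches its table target.
#' The energy offset is then fixed so that the GC minimum sits exactly at
#' zero. The fit is deterministic; `seed` is recorded with the result and
#' seeds the (deterministic) optimiser restarts.
#'
#' @param targets data.frame with columns state, energy_eV and optionally
#'   tolerance_eV (default 0.02 eV), e.g. from [stationary_table()];
#'   must contain a GC row with energy 0
#' @param init optional starting `dpt_surface` (default: wells/saddles as
#'   listed in `targets`)
#' @param seed integer, recorded in the calibration metadata
#' @param maxit Nelder-Mead iteration cap
#' @param geom,shape passed to [surface_params()] when `init` is NULL
#' @return calibrated `dpt_surface`; `$calibration` holds targets,
#'   residuals, seed and convergence details
#' @export
calibrate_surface <- function(targets, init = NULL, seed = 1L,
                              maxit = 5000, geom = geometry_refs(),
                              shape = list(), kind = NULL) {
  if (is.character(targets) && length(targets) == 1)
    targets <- stationary_table(targets)
  scenario <- if ("scenario" %in% names(targets) && nrow(targets))
    targets$scenario[1] else "custom"
  if (is.null(kind))
    kind <- if (grepl("frozen", scenario)) "frozen" else "thermal"
  if (is.null(targets$tolerance_eV)) targets$tolerance_eV <- 0.02
  if (!"GC" %in% targets$state)
    stop("calibration targets must include the GC reference state")
  if (any(!is.finite(targets$energy_eV)) || any(targets$tolerance_eV <= 0))
    stop("calibration targets must have finite energies and positive tolerances")
  if (abs(targets$energy_eV[targets$state == "GC"]) > 1e-9)
    stop("GC target energy must be 0 (reference convention)")

  min_all <- c("GC", "G_minus_C_plus", "G_plus_C_minus", "GstarCstar")
  sad_all <- c("TS1", "TS2", "SYNC_TS")
  tmin <- intersect(min_all, targets$state)
  tsad <- intersect(sad_all, targets$state)
  unknown <- setdiff(targets$state, c(min_all, sad_all))
  if (length(unknown)) stop("unknown states in targets: ",
                            paste(unknown, collapse = ", "))
  if (is.null(init))
    init <- surface_params(states = setdiff(tmin, "GC"), saddles = tsad,
                           geom = geom, shape = shape, scenario = scenario,
                           kind = kind)
  params <- init
  params$scenario <- scenario

  fit_states <- c(setdiff(tmin, "GC"), tsad)
  goal <- setNames(targets$energy_eV, targets$state)

  apply_theta <- function(p, theta) {
    nr <- length(setdiff(tmin, "GC"))
    if (nr) {
      idx <- match(setdiff(tmin, "GC"), p$ramps$state)
      p$ramps$amp[idx] <- theta[seq_len(nr)]
    }
    if (length(tsad)) {
      idx <- match(tsad, p$bumps$state)
      p$bumps$amp[idx] <- theta[nr + seq_along(tsad)]
    }
    p
  }
  pos <- state_positions(geom)
  ## stationary points with validity screening: a state's minimum must stay
  ## within its own neighbourhood and a saddle must have Hessian index 1,
  ## otherwise the candidate surface has lost that feature. Moderate drift
  ## is softly penalised so the optimiser keeps gradient information near
  ## the feasibility boundary.
  measure <- function(p, max_drift = 0.45) {
    st <- tryCatch(stationary_energies(p, states = c(tmin, tsad)),
                   error = function(e) NULL)
    if (is.null(st)) return(NULL)
    dom <- geom$domain
    pen <- 0
    for (i in seq_len(nrow(st))) {
      ref <- pos[[st$state[i]]]
      drift <- sqrt((st$r1[i] - ref[1])^2 + (st$r2[i] - ref[2])^2)
      want_idx <- if (st$state[i] %in% sad_all) 1L else 0L
      if (drift > max_drift || st$index[i] != want_idx) return(NULL)
      pen <- pen + 50 * max(0, drift - 0.36)^2
      ## every stationary feature must live inside the sampled domain
      out <- max(0, dom[1] + 0.02 - min(st$r1[i], st$r2[i])) +
             max(0, max(st$r1[i], st$r2[i]) - (dom[2] - 0.02))
      if (out > 0.08) return(NULL)
      pen <- pen + 200 * out^2
    }
    list(e = setNames(st$energy_eV, st$state), penalty = pen)
  }
  objective <- function(theta) {
    m <- measure(apply_theta(params, theta))
    if (is.null(m) || !all(fit_states %in% names(m$e))) return(1e6)
    sum((m$e[fit_states] - goal[fit_states])^2) + m$penalty
  }
  ## energies are linear in the amplitudes at fixed stationary positions;
  ## an iterated linear solve gives a near-exact start for the simplex fit
  basis_matrix <- function(p, at) {
    nr <- length(setdiff(tmin, "GC"))
    cols <- list()
    gphi <- function(ctr, w, xy)
      exp(-((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) / (2 * w^2))
    for (sn in setdiff(tmin, "GC"))
      cols[[sn]] <- gphi(pos[[sn]], p$shape$ramp_width, at)
    for (sn in tsad)
      cols[[sn]] <- gphi(pos[[sn]], p$shape$bump_width, at)
    do.call(cbind, cols)
  }
  linear_step <- function(theta) {
    p <- apply_theta(params, theta)
    st <- tryCatch(stationary_energies(p, states = c(tmin, tsad),
                                       relative = FALSE),
                   error = function(e) NULL)
    at <- t(vapply(c("GC", fit_states), function(sn) {
      if (!is.null(st) && sn %in% st$state) {
        i <- which(st$state == sn)
        d <- sqrt((st$r1[i] - pos[[sn]][1])^2 + (st$r2[i] - pos[[sn]][2])^2)
        if (d <= 0.40) return(c(st$r1[i], st$r2[i]))
      }
      pos[[sn]]   # escaped or missing: anchor at the reference position
    }, numeric(2)))
    p0 <- apply_theta(params, 0 * theta)
    base <- surface_evaluate(p0, at[, 1], at[, 2], check = FALSE)
    A <- basis_matrix(params, at)
    Arel <- sweep(A[-1, , drop = FALSE], 2, A[1, ])
    brel <- goal[fit_states] - (base[-1] - base[1])
    tryCatch(drop(solve(qr(Arel, LAPACK = TRUE), brel)),
             error = function(e) theta)
  }
  linear_init <- function() {
    theta <- setNames(rep(0, length(fit_states)), fit_states)
    best <- theta; best_obj <- Inf
    for (it in 1:40) {
      new <- linear_step(theta)
      theta <- setNames(theta + 0.7 * (new - theta), fit_states) # damped
      ob <- objective(theta)
      if (ob < best_obj) { best <- theta; best_obj <- ob }
      if (best_obj < 1e-10 || max(abs(new - theta)) < 1e-7) break
    }
    best
  }

  if (length(fit_states)) {
    set.seed(seed)
    theta0 <- linear_init()
    ob0 <- objective(theta0)
    if (!is.finite(ob0) || ob0 >= 1e6) {
      theta0 <- setNames(rep(0, length(fit_states)), fit_states)
      ob0 <- objective(theta0)
    }
    if (ob0 < 1e-8) {
      ## linear initialisation already at numerical resolution
      fit <- list(par = theta0, value = ob0, counts = c(0L, NA))
    } else {
      fit <- optim(theta0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12))
      ## alternate a linear refit with a second simplex polish
      th1 <- linear_step(fit$par)
      if (objective(th1) < fit$value) fit$par <- setNames(th1, fit_states)
      fit <- optim(fit$par, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-14))
    }
    params <- apply_theta(params, fit$par)
  } else fit <- list(par = numeric(0), value = 0, counts = c(0, NA))

  ## fix the energy reference: E(GC minimum) = 0
  sf <- as_surface_fun(params)
  gcmin <- find_min_2d(sf, unlist(params$wells[params$wells$state == "GC",
                                               c("x", "y")]))
  params$offset <- params$offset - gcmin$energy

  meas <- stationary_energies(params, states = c(tmin, tsad))
  resid <- meas$energy_eV - goal[meas$state]
  bad <- abs(resid) > targets$tolerance_eV[match(meas$state, targets$state)]
  if (any(bad, na.rm = TRUE))
    stop("calibration failure: residuals exceed tolerance\n",
         paste(sprintf("  %-15s target %6.3f  got %6.3f  (resid %+.4f)",
                       meas$state, goal[meas$state], meas$energy_eV, resid),
               collapse = "\n"))
  params$calibration <- list(
    targets = targets, seed = seed,
    residuals = setNames(resid, meas$state),
    stationary = meas, objective = fit$value,
    evaluations = unname(fit$counts[1]))
  params
}

#' @export
print.dpt_surface <- function(x, ...) {
  cat(sprintf("<dpt_surface> scenario '%s'\n", x$scenario))
  cat(sprintf("  wells: %s\n", paste(x$wells$state, collapse = ", ")))
  if (nrow(x$bumps))
    cat(sprintf("  saddles: %s\n", paste(x$bumps$state, collapse = ", ")))
  if (!is.null(x$calibration)) {
    r <- x$calibration$residuals
    cat(sprintf("  calibrated (seed %d), max |residual| %.4f eV\n",
                x$calibration$seed, max(abs(r))))
  } else cat("  uncalibrated\n")
  invisible(x)
}
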