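## Shared fixtures: calibrated surfaces are expensive, cache them per
## session; small constructor helpers for synthetic test surfaces.

.calib_cache <- new.env(parent = emptyenv())

calib <- function(scenario) {
  if (is.null(.calib_cache[[scenario]]))
    .calib_cache[[scenario]] <- calibrate_surface(stationary_table(scenario))
  .calib_cache[[scenario]]
}

## isotropic harmonic test surface: pure quadratic confinement, stiffness
## k_harm = 2 * c0, centred mid-domain, no wells or ridges
harmonic_surface <- function(c0 = 1.0) {
  surface_params(states = character(0), saddles = character(0),
                 shape = list(gc_depth = 0, well_depth = 0, conf_c0 = c0,
                              sync_amp = 0),
                 scenario = "harmonic_test")
}

## two-basin test surface along r1 with a controlled energy split
two_basin_surface <- function(dE = 0.05, depth = 0.25, width = 0.30) {
  p <- surface_params(states = character(0), saddles = character(0),
                      shape = list(gc_depth = 0, well_depth = 0,
                                   conf_c0 = 0.8, sync_amp = 0),
                      scenario = "two_basin_test")
  p$wells <- data.frame(
    state = c("A", "B"),
    x = c(1.35, 2.05), y = c(1.7, 1.7),
    depth = c(depth + dE, depth), w = width, stringsAsFactors = FALSE)
  p
}

## minima of the four-state scenarios, located once
scenario_minima <- function(scenario) {
  key <- paste0(scenario, "_minima")
  if (is.null(.calib_cache[[key]]))
    .calib_cache[[key]] <- find_minima(calib(scenario))
  .calib_cache[[key]]
}

min_pos <- function(mins, state)
  unlist(mins[mins$state == state, c("r1", "r2")])

## independent minimax (bottleneck) oracle over ALL 4-connected grid paths:
## flood the grid in order of increasing energy (union-find) and report the
## level at which the two endpoints join. The true minimum-energy-path
## saddle may be non-monotone in the coordinates, so all paths must be
## admitted.
dp_minimax_oracle <- function(params, from, to, n = 201, pad = 0.15, s = 0) {
  lo <- pmax(pmin(from, to) - pad, params$geom$domain[1])
  hi <- pmin(pmax(from, to) + pad, params$geom$domain[2])
  xs <- seq(lo[1], hi[1], length.out = n)
  ys <- seq(lo[2], hi[2], length.out = n)
  E <- outer(xs, ys, function(a, b) surface_evaluate(params, a, b, s = s,
                                                     check = FALSE))
  id <- function(i, j) (j - 1L) * n + i
  a <- id(which.min(abs(xs - from[1])), which.min(abs(ys - from[2])))
  b <- id(which.min(abs(xs - to[1])),   which.min(abs(ys - to[2])))
  parent <- seq_len(n * n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  active <- logical(n * n)
  ord <- order(E)
  for (k in ord) {
    active[k] <- TRUE
    i <- ((k - 1L) %% n) + 1L; j <- ((k - 1L) %/% n) + 1L
    for (nb in c(if (i > 1) k - 1L, if (i < n) k + 1L,
                 if (j > 1) k - n, if (j < n) k + n))
      if (active[nb]) {
        ra <- find(k); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    if (active[a] && active[b] && find(a) == find(b)) return(E[k])
  }
  stop("bottleneck search failed to connect endpoints")
}

quiet_series <- function(...) {
  withCallingHandlers(run_umbrella_series(...),
                      warning = function(w) invokeRestart("muffleWarning"))
}
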