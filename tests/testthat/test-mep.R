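test_that("grid sampling is a direct evaluation with complete metadata", {
  p <- calib("duplex_frozen")
  g <- sample_grid(p, 33)
  expect_equal(dim(g$E), c(33, 33))
  expect_equal(length(g$E), 1089)
  expect_false(g$too_coarse)
  ## the lowest node sits in the GC quadrant
  i <- which(g$E == min(g$E), arr.ind = TRUE)
  expect_lt(g$r1[i[1]], p$geom$R_NN / 2)
  expect_lt(g$r2[i[2]], p$geom$R_ON / 2)
  ## degenerate 2x2 grid is flagged too coarse
  g2 <- sample_grid(p, 2)
  expect_true(g2$too_coarse)
  expect_warning(find_minima(interpolate_grid(g2)), "coarse")
  ## constant surface away from the compression walls: equal energies
  flat <- harmonic_surface(c0 = 0)
  gf <- sample_grid(flat, 33)
  inner <- gf$r1 > 1.0 & gf$r1 < 1.95
  expect_equal(max(gf$E[inner, inner]) - min(gf$E[inner, inner]), 0)
})

test_that("the interpolant is node-exact, reproduces linear data, and is accurate", {
  p <- calib("duplex_frozen")
  g <- sample_grid(p, 33)
  it <- interpolate_grid(g)
  ## node exactness
  idx <- cbind(c(1, 10, 17, 33), c(5, 10, 30, 33))
  for (k in seq_len(nrow(idx)))
    expect_equal(it$f(g$r1[idx[k, 1]], g$r2[idx[k, 2]]),
                 g$E[idx[k, 1], idx[k, 2]], tolerance = 1e-12)
  ## linear (bilinear, separable) data reproduced to rounding
  glin <- g
  glin$E <- outer(g$r1, g$r2, function(a, b) 0.3 + 1.2 * a - 0.7 * b)
  itl <- interpolate_grid(glin)
  set.seed(1)
  qx <- runif(20, 0.9, 2.5); qy <- runif(20, 0.9, 2.5)
  expect_lt(max(abs(itl$f(qx, qy) - (0.3 + 1.2 * qx - 0.7 * qy))), 1e-10)
  ## off-node queries against the generating surface
  set.seed(2)
  qx <- runif(150, 0.95, 2.45); qy <- runif(150, 0.95, 2.45)
  expect_lt(max(abs(it$f(qx, qy) -
                    surface_evaluate(p, qx, qy, check = FALSE))), 0.01)
  expect_error(it$f(0.5, 1.2), "hull")
})

test_that("find_minima locates the scenario minima and no spurious ones", {
  mins <- scenario_minima("duplex_frozen")
  expect_setequal(mins$state, c("GC", "G_minus_C_plus", "GstarCstar"))
  expect_false("G_plus_C_minus" %in% mins$state)
  expect_true(all(mins$grad_norm < 1e-4))
  ## against a dense local grid search (brute-force oracle)
  p <- calib("duplex_frozen")
  for (i in seq_len(nrow(mins))) {
    gx <- seq(mins$r1[i] - 0.05, mins$r1[i] + 0.05, by = 0.002)
    gy <- seq(mins$r2[i] - 0.05, mins$r2[i] + 0.05, by = 0.002)
    Eg <- outer(gx, gy, function(a, b) surface_evaluate(p, a, b, check = FALSE))
    expect_lt(abs(min(Eg) - mins$energy_eV[i]), 1e-3)
  }
  ## single-well surface: one minimum regardless of starts
  h <- harmonic_surface(c0 = 1.0)
  m1 <- find_minima(h)
  expect_equal(nrow(m1), 1L)
})

test_that("NEB follows the symmetry-forced straight path on a symmetric double well", {
  p <- surface_params(states = character(0), saddles = character(0),
                      shape = list(gc_depth = 0, well_depth = 0,
                                   conf_c0 = 0.5, sync_amp = 0))
  p$wells <- data.frame(state = c("A", "B"), x = c(1.25, 2.15),
                        y = c(1.7, 1.7), depth = 0.6, w = 0.28,
                        stringsAsFactors = FALSE)
  mep <- neb_path(p, c(1.25, 1.7), c(2.15, 1.7), via = "synchronous")
  expect_true(mep$converged)
  expect_lt(max(abs(mep$images[, 2] - 1.7)), 0.01)
})

test_that("NEB saddles agree with the dynamic-programming minimax oracle", {
  for (sc in c("duplex_frozen", "helicaseN_frozen", "helicaseN_thermal")) {
    p <- calib(sc)
    mins <- scenario_minima(sc)
    mep <- neb_path(p, min_pos(mins, "GC"), min_pos(mins, "GstarCstar"))
    dp <- dp_minimax_oracle(p, min_pos(mins, "GC"),
                            min_pos(mins, "GstarCstar"))
    expect_lt(abs(max(mep$energy) - dp), 0.01)
    ## highest interior image is a converged climbing image
    sf <- as_surface_fun(p)
    ci <- which.max(mep$energy[2:(mep$n_images - 1)]) + 1
    g <- sf$g(mep$images[ci, 1], mep$images[ci, 2])
    expect_lt(sqrt(sum(g^2)), 5e-3)
  }
})

test_that("the helicase-N frozen path steps first into the zwitterion at 1.35 eV", {
  p <- calib("helicaseN_frozen")
  mins <- scenario_minima("helicaseN_frozen")
  mep <- neb_path(p, min_pos(mins, "GC"), min_pos(mins, "GstarCstar"),
                  via = "G_minus_C_plus")
  expect_equal(mep$via, "G_minus_C_plus")
  prof <- analyze_profile(mep)
  zw <- prof$stationary
  expect_equal(zw$G_eV[zw$state == "G_minus_C_plus"], 1.35,
               tolerance = 0.02)
})

test_that("the path is reversible and stable under image refinement", {
  p <- calib("duplex_frozen")
  mins <- scenario_minima("duplex_frozen")
  fwd <- neb_path(p, min_pos(mins, "GC"), min_pos(mins, "GstarCstar"))
  rev <- neb_path(p, min_pos(mins, "GstarCstar"), min_pos(mins, "GC"))
  ## reversed path visits the same curve (Hausdorff-style comparison)
  d <- vapply(seq_len(nrow(rev$images)), function(i)
    min(sqrt((fwd$images[, 1] - rev$images[i, 1])^2 +
             (fwd$images[, 2] - rev$images[i, 2])^2)), 0)
  expect_lt(max(d), 0.05)
  expect_equal(max(rev$energy), max(fwd$energy), tolerance = 1e-3)
  ## doubling the image count barely moves the barrier
  fwd64 <- neb_path(p, min_pos(mins, "GC"), min_pos(mins, "GstarCstar"),
                    n_images = 64)
  expect_lt(abs(max(fwd64$energy) - max(fwd$energy)), 0.005)
})

test_that("the grid pipeline reproduces the analytic pipeline", {
  p <- calib("helicaseN_frozen")
  g <- sample_grid(p, 33)
  it <- interpolate_grid(g)
  ma <- find_minima(p)
  mg <- find_minima(it)
  common <- intersect(ma$state, mg$state)
  expect_true(all(c("GC", "G_minus_C_plus", "GstarCstar") %in% common))
  for (stt in common) {
    ea <- ma$energy_eV[ma$state == stt] - ma$energy_eV[ma$state == "GC"]
    eg <- mg$energy_eV[mg$state == stt] - mg$energy_eV[mg$state == "GC"]
    expect_lt(abs(ea - eg), 0.01)
  }
})
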