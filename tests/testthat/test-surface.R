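test_that("calibrated surfaces place GC at zero and hit their targets", {
  p <- calib("duplex_thermal")
  st <- p$calibration$stationary
  expect_lt(abs(st$energy_eV[st$state == "GC"]), 1e-6)
  expect_equal(st$energy_eV[st$state == "GstarCstar"], 0.60,
               tolerance = 0.02)
  expect_true(all(abs(p$calibration$residuals) <= 0.02))
  expect_error(surface_evaluate(p, 0.5, 1.2), "domain")
  expect_error(surface_evaluate(p, 1.2, 1.2, s = -0.1))
})

test_that("mirror-symmetric parameters give a mirror-symmetric energy", {
  geom <- geometry_refs(R_NN = 2.94, R_ON = 2.94)
  p <- surface_params(states = c("G_minus_C_plus", "G_plus_C_minus",
                                 "GstarCstar"),
                      saddles = character(0), geom = geom,
                      shape = list(sync_amp = 0.5))
  ## equal amplitudes on the two mirror-image zwitterions
  p$ramps$amp <- c(0.4, 0.4, 0.7)
  r1 <- c(1.1, 1.4, 1.9, 2.2); r2 <- c(1.3, 1.0, 1.5, 1.8)
  expect_equal(surface_evaluate(p, r1, r2), surface_evaluate(p, r2, r1))
})

test_that("analytic gradient matches central finite differences", {
  p <- calib("helicaseN_frozen")
  set.seed(42)
  r1 <- runif(25, 1.0, 2.3); r2 <- runif(25, 1.0, 2.3)
  g <- surface_gradient(p, r1, r2, s = 0.2)
  h <- 1e-5
  fd1 <- (surface_evaluate(p, r1 + h, r2, s = 0.2, check = FALSE) -
          surface_evaluate(p, r1 - h, r2, s = 0.2, check = FALSE)) / (2 * h)
  fd2 <- (surface_evaluate(p, r1, r2 + h, s = 0.2, check = FALSE) -
          surface_evaluate(p, r1, r2 - h, s = 0.2, check = FALSE)) / (2 * h)
  expect_lt(max(abs(g[, 1] - fd1) / pmax(abs(fd1), 1)), 1e-4)
  expect_lt(max(abs(g[, 2] - fd2) / pmax(abs(fd2), 1)), 1e-4)
  ## stationary at the calibrated GC minimum
  st <- p$calibration$stationary
  gmin <- surface_gradient(p, st$r1[st$state == "GC"],
                           st$r2[st$state == "GC"])
  expect_lt(sqrt(sum(gmin^2)), 1e-4)
  ## quadratic-only surface: gradient is exactly linear
  hq <- harmonic_surface(c0 = 1.3)
  gq <- surface_gradient(hq, c(1.2, 1.9), c(1.5, 1.75))
  expect_equal(gq[, 1], 2 * 1.3 * (c(1.2, 1.9) - 1.7))
  expect_equal(gq[, 2], 2 * 1.3 * (c(1.5, 1.75) - 1.7))
})

test_that("calibration reproduces the spec'd example target sets", {
  duplex <- data.frame(
    state = c("GC", "TS1", "G_minus_C_plus", "GstarCstar"),
    energy_eV = c(0, 0.60, 0.55, 0.60), tolerance_eV = 0.02)
  p <- calibrate_surface(duplex, kind = "thermal")
  expect_true(all(abs(p$calibration$residuals) <= 0.02))

  helN <- data.frame(
    state = c("GC", "G_minus_C_plus", "TS1", "GstarCstar", "TS2"),
    energy_eV = c(0, 1.35, 1.38, 1.78, 2.76), tolerance_eV = 0.02)
  pf <- calibrate_surface(helN, kind = "frozen")
  expect_true(all(abs(pf$calibration$residuals) <= 0.02))
  idx <- setNames(pf$calibration$stationary$index,
                  pf$calibration$stationary$state)
  expect_equal(unname(idx[c("GC", "G_minus_C_plus", "GstarCstar")]),
               c(0L, 0L, 0L))
  expect_equal(unname(idx[c("TS1", "TS2")]), c(1L, 1L))

  ## degenerate target set: GC alone is an identity fit
  p0 <- calibrate_surface(data.frame(state = "GC", energy_eV = 0,
                                     tolerance_eV = 0.02))
  expect_lt(abs(stationary_energies(p0)$energy_eV[1]), 1e-9)
  expect_error(calibrate_surface(data.frame(state = "GstarCstar",
                                            energy_eV = 1)),
               "GC")
})

test_that("calibrating against a surface's own stationary energies recovers it", {
  p <- calib("n624a_frozen")
  meas <- stationary_energies(p)
  targets <- data.frame(state = meas$state, energy_eV = meas$energy_eV,
                        tolerance_eV = 0.02)
  targets$energy_eV[targets$state == "GC"] <- 0
  p2 <- calibrate_surface(targets, kind = "frozen")
  meas2 <- stationary_energies(p2)
  m <- match(meas$state, meas2$state)
  expect_true(all(abs(meas$energy_eV - meas2$energy_eV[m]) <= 0.02))
})

test_that("all downstream energies are invariant to a constant offset", {
  p <- calib("duplex_frozen")
  p2 <- p
  p2$offset <- p2$offset + 3.7
  s1 <- stationary_energies(p)        # relative to GC
  s2 <- stationary_energies(p2)
  expect_equal(s1$energy_eV, s2$energy_eV, tolerance = 1e-8)
})

test_that("separation raises the transition states and zwitterion monotonically", {
  p <- calib("helicaseN_frozen")
  svals <- c(0, 0.2, 0.4, 0.6)
  E <- sapply(svals, function(sv) {
    st <- stationary_energies(p, s = sv)
    setNames(st$energy_eV, st$state)[c("TS1", "TS2", "G_minus_C_plus")]
  })
  for (i in 1:3) expect_true(all(diff(E[i, ]) > -1e-6))
  ## coupling vanishes at s = 0
  expect_equal(surface_evaluate(p, 1.3, 1.4, s = 0),
               .subset2(as_surface_fun(p, s = 0), "f")(1.3, 1.4))
})

test_that("surfaces serialize to YAML and back without loss", {
  p <- calib("duplex_thermal")
  tf <- tempfile(fileext = ".yaml")
  write_surface(p, tf)
  p2 <- read_surface(tf)
  r1 <- c(1.0, 1.5, 2.1); r2 <- c(1.2, 1.8, 1.1)
  expect_equal(surface_evaluate(p2, r1, r2, s = 0.3),
               surface_evaluate(p, r1, r2, s = 0.3), tolerance = 1e-12)
})
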