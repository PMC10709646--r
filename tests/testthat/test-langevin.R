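test_that("at T = 0 an unbiased trajectory descends into the GC minimum", {
  p <- calib("duplex_thermal")
  st0 <- simulation_settings(temperature = 0, n_steps = 6000, burn_in = 0,
                             store_stride = 10, seed = 7)
  tr <- simulate_dpt(p, st0, start = c(1.1, 1.08))
  gc <- p$calibration$stationary
  gc <- gc[gc$state == "GC", ]
  expect_lt(abs(tail(tr$r1_A, 1) - gc$r1), 0.01)
  expect_lt(abs(tail(tr$r2_A, 1) - gc$r2), 0.01)
})

test_that("equipartition holds on the harmonic test surface", {
  h <- harmonic_surface(c0 = 1.0)            # k_harm = 2 eV/A^2
  st <- simulation_settings(friction = 20, n_steps = 400000, burn_in = 4000,
                            store_stride = 4, seed = 3)
  tr <- simulate_dpt(h, st, start = c(1.7, 1.7))
  kBT <- dpt_constants$kB * 310
  expect_equal(var(tr$r1_A) / (kBT / 2), 1, tolerance = 0.05)
  expect_equal(var(tr$r2_A) / (kBT / 2), 1, tolerance = 0.05)
})

test_that("halving the timestep leaves the sampled variance unchanged", {
  h <- harmonic_surface(c0 = 1.0)
  st1 <- simulation_settings(friction = 20, dt = 0.5, n_steps = 20000000,
                             burn_in = 10000, store_stride = 20, seed = 5)
  st2 <- simulation_settings(friction = 20, dt = 0.25, n_steps = 40000000,
                             burn_in = 20000, store_stride = 40, seed = 6)
  v1 <- var(simulate_dpt(h, st1, start = c(1.7, 1.7))$r1_A)
  v2 <- var(simulate_dpt(h, st2, start = c(1.7, 1.7))$r1_A)
  expect_equal(v2 / v1, 1, tolerance = 0.01)
})

test_that("trajectories are byte-identical under a fixed seed", {
  p <- calib("duplex_thermal")
  st <- simulation_settings(n_steps = 5000, seed = 11, burn_in = 1000)
  t1 <- simulate_dpt(p, st)
  t2 <- simulate_dpt(p, st)
  expect_identical(t1$r1_A, t2$r1_A)
  expect_identical(t1$E_eV, t2$E_eV)
})

test_that("an umbrella window at the canonical references restrains lambda near 0", {
  p <- calib("duplex_thermal")
  geom <- p$geom
  w <- umbrella_window(geom$d_GC, geom = geom)
  st <- simulation_settings(n_steps = 8000, burn_in = 2000, seed = 9)
  tr <- simulate_dpt(p, st, window = w)
  expect_lt(abs(mean(tr$lambda)), 0.05)
})

test_that("window series bookkeeping: counts, distinct seeds, stiffer restraints", {
  p <- calib("duplex_thermal")
  st <- simulation_settings(n_steps = 3000, burn_in = 500, seed = 13)
  trajs <- quiet_series(p, st, n_windows = 10, replicas = 2,
                        min_overlap = 0)
  expect_length(trajs, 20)
  seeds <- vapply(trajs, function(t) attr(t, "settings")$seed, 0L)
  expect_equal(anyDuplicated(seeds), 0L)
  ## lambda histograms cover [0, 1] without gaps (connectivity held)
  trajs24 <- quiet_series(p, st, n_windows = 24, replicas = 2)
  lam <- unlist(lapply(trajs24, function(t) t$lambda))
  expect_lt(max(diff(sort(lam[lam > -0.05 & lam < 1.05]))), 0.05)
  ## doubling k narrows the per-window lambda spread
  sd_of <- function(k) {
    tr <- quiet_series(p, st, n_windows = 8, replicas = 1, k = k,
                       min_overlap = 0)
    mean(vapply(tr, function(t) sd(t$lambda), 0))
  }
  expect_lt(sd_of(40000), sd_of(20000))
})

test_that("unbiased basin occupancy matches the Boltzmann ratio", {
  p <- two_basin_surface(dE = 0.04)
  st <- simulation_settings(n_steps = 4000000, burn_in = 10000,
                            store_stride = 10, seed = 21)
  tr <- simulate_dpt(p, st, start = c(1.35, 1.7))
  split <- 1.7                     # midpoint between the two basins in r1
  ratio_sim <- mean(tr$r1_A > split) / mean(tr$r1_A < split)
  ## quadrature oracle on the same surface
  g <- seq(0.9, 2.5, by = 0.005)
  gr <- expand.grid(r1 = g, r2 = g)
  w <- exp(-surface_evaluate(p, gr$r1, gr$r2, check = FALSE) /
             (dpt_constants$kB * 310))
  ratio_exact <- sum(w[gr$r1 > split]) / sum(w[gr$r1 < split])
  expect_equal(ratio_sim / ratio_exact, 1, tolerance = 0.15)
})

test_that("steered separation follows the imposed schedule", {
  p <- calib("helicaseN_frozen")
  st <- simulation_settings(n_steps = 10000, burn_in = 0, store_stride = 5,
                            seed = 31)
  ## zero pull: no separation
  tr0 <- steered_separation(p, st, max_s = 0)
  expect_true(all(tr0$s_A == 0))
  ## 5 ps pull reaching max_s, with snapshots at the printed separations
  tr <- steered_separation(p, st, max_s = 0.6, pull_rate = 0.15)
  expect_equal(tail(tr$s_A, 1), 0.6)
  expect_true(all(diff(tr$s_A) >= 0))
  for (starget in c(0.23, 0.60))
    expect_lt(min(abs(tr$s_A - starget)), 0.01)
  ## doubling the rate halves the time to a given separation
  t_reach <- function(rate) {
    trr <- steered_separation(p, st, max_s = 0.6, pull_rate = rate)
    trr$t_fs[which(trr$s_A >= 0.3)[1]]
  }
  expect_equal(t_reach(0.30) / t_reach(0.15), 0.5, tolerance = 0.05)
})

test_that("decay runs are deterministic and trap at T = 0 behind a barrier", {
  pf <- calib("duplex_frozen")       # frozen tautomer has a reverse barrier
  mn <- scenario_minima("duplex_frozen")
  start <- min_pos(mn, "GstarCstar")
  st <- simulation_settings(n_steps = 2000, burn_in = 0, store_stride = 1,
                            seed = 17)
  d1 <- decay_run(pf, start, st, n_replicas = 3)
  d2 <- decay_run(pf, start, st, n_replicas = 3)
  expect_identical(d1$first_passage, d2$first_passage)
  st0 <- simulation_settings(temperature = 0, n_steps = 2000, burn_in = 0,
                             store_stride = 1, seed = 17)
  d0 <- decay_run(pf, start, st0, n_replicas = 3)
  expect_false(any(d0$first_passage$decayed))
})

test_that("excessive boundary reflections are reported", {
  h <- harmonic_surface(c0 = 0.02)   # nearly flat background
  geom <- geometry_refs()
  ## a stiff restraint pulling beyond the domain edge presses the proton
  ## against the reflective boundary
  w <- umbrella_window(c(0.55, geom$R_NN - 0.55, 1.7, geom$R_ON - 1.7),
                       k = 3e5, geom = geom)
  st <- simulation_settings(n_steps = 20000, burn_in = 0, seed = 23)
  expect_warning(simulate_dpt(h, st, window = w, start = c(0.95, 1.7)),
                 "reflective")
})
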