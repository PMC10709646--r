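test_that("a single unbiased window degenerates to Boltzmann inversion", {
  p <- two_basin_surface(dE = 0.03, depth = 0.20)
  geom <- geometry_refs()
  w <- umbrella_window(geom$d_GC, k = 1e-6, geom = geom)   # negligible bias
  st <- simulation_settings(n_steps = 400000, burn_in = 4000,
                            store_stride = 4, seed = 3)
  tr <- simulate_dpt(p, st, window = w, start = c(1.35, 1.7))
  pmf <- wham_pmf(list(tr), bins = 60, lambda_range = range(tr$lambda),
                  path = "none")
  ## reference: plain histogram inversion of the same frames
  br <- seq(min(tr$lambda), max(tr$lambda), length.out = 61)
  h <- hist(tr$lambda, breaks = br, plot = FALSE)$counts
  Gref <- -dpt_constants$kB * 310 * log(h)
  Gref <- Gref - min(Gref[h > 0])
  ok <- pmf$n >= 200 & h >= 200
  expect_lt(max(abs(pmf$G_eV[ok] - Gref[ok])), 0.02)
})

test_that("WHAM recovers the closed-form marginal of a harmonic surface", {
  c0 <- 2.0
  h <- harmonic_surface(c0 = c0)
  geom <- geometry_refs()
  st <- simulation_settings(n_steps = 16000, seed = 5)
  lam0 <- lambda_of(1.7, 1.7, geom)
  trajs <- quiet_series(h, st, n_windows = 12,
                        lambda_range = lam0 + c(-0.35, 0.35),
                        replicas = 2, path = "synchronous")
  pmf <- wham_pmf(trajs, bins = 80, lambda_range = lam0 + c(-0.35, 0.35),
                  path = "synchronous")
  ## closed form: lambda is a linear image of a Gaussian, so
  ## G = kT (lambda - lam0)^2 / (2 var), var = (a1^2 + a2^2) kT / (2 c0)
  kBT <- dpt_constants$kB * 310
  a1 <- 0.5 / (geom$R_NN - 2 * geom$r_cov)
  a2 <- 0.5 / (geom$R_ON - 2 * geom$r_cov)
  vlam <- (a1^2 + a2^2) * kBT / (2 * c0)
  Gth <- (pmf$lambda - lam0)^2 / (2 * vlam) * kBT
  Gth <- Gth - min(Gth[is.finite(pmf$G_eV)])
  ok <- is.finite(pmf$G_eV) & pmf$n >= 100
  expect_lt(sqrt(mean((pmf$G_eV[ok] - Gth[ok])^2)), 0.01)
})

test_that("the profile is gauge invariant and permutation invariant", {
  p <- calib("duplex_thermal")
  st <- simulation_settings(n_steps = 4000, burn_in = 1000, seed = 7)
  trajs <- quiet_series(p, st, n_windows = 12, replicas = 2,
                        min_overlap = 0)
  prep <- gcdpt:::.wham_prep(trajs)
  sol <- gcdpt:::.wham_solve(prep, prep$counts)
  base <- gcdpt:::.wham_bin(prep, sol$w, prep$counts, 120, c(-0.1, 1.1))
  ## add an arbitrary constant to every bias potential
  prep2 <- prep
  prep2$B <- prep2$B + 1.23
  sol2 <- gcdpt:::.wham_solve(prep2, prep2$counts)
  alt <- gcdpt:::.wham_bin(prep2, sol2$w, prep2$counts, 120, c(-0.1, 1.1))
  ok <- is.finite(base$G_eV)
  expect_lt(max(abs(base$G_eV[ok] - alt$G_eV[ok])), 1e-10)
  ## trajectory order must not matter
  pmf_a <- wham_pmf(trajs)
  pmf_b <- wham_pmf(rev(trajs))
  expect_equal(pmf_a$G_eV, pmf_b$G_eV, tolerance = 1e-10)
})

test_that("block bootstrap yields finite spreads and flags the degenerate case", {
  p <- calib("duplex_thermal")
  st <- simulation_settings(n_steps = 4000, burn_in = 1000, seed = 9)
  trajs <- quiet_series(p, st, n_windows = 12, replicas = 2,
                        min_overlap = 0)
  bb <- bootstrap_pmfs(trajs, n_boot = 20, seed = 1)
  expect_length(bb$replicates, 20)
  ok <- is.finite(bb$pmf$G_eV)
  expect_true(all(bb$pmf$sigma_eV[ok] >= 0))
  expect_true(any(bb$pmf$sigma_eV[ok] > 0))
  expect_warning(b1 <- bootstrap_pmfs(trajs, n_boot = 1, seed = 1),
                 "degenerate")
  expect_true(all(b1$pmf$sigma_eV[is.finite(b1$pmf$sigma_eV)] == 0))
})

test_that("more sampling shrinks the bootstrap uncertainty", {
  p <- calib("duplex_thermal")
  pmf_of <- function(steps, sd) {
    st <- simulation_settings(n_steps = steps, burn_in = 1000, seed = sd)
    trajs <- quiet_series(p, st, n_windows = 16, replicas = 2,
                          min_overlap = 0)
    bootstrap_pmfs(trajs, n_boot = 15, seed = 2)$pmf
  }
  short <- pmf_of(3000, 11)
  long <- pmf_of(16000, 11)
  ## compare on bins both runs resolve
  ok <- is.finite(short$G_eV) & is.finite(long$G_eV) &
    short$n >= 200 & long$n >= 200
  expect_lt(mean(long$sigma_eV[ok]), mean(short$sigma_eV[ok]))
})

test_that("the logistic convergence diagnostic behaves at its fixed points", {
  p <- calib("duplex_thermal")
  st <- simulation_settings(n_steps = 4000, burn_in = 1000, seed = 13)
  trajs <- quiet_series(p, st, n_windows = 12, replicas = 2,
                        min_overlap = 0)
  pmf <- wham_pmf(trajs)
  ## identical profiles at every time: rms identically zero, converged
  same <- list(pmf, pmf, pmf, pmf, pmf)
  cc <- convergence_check(same, times = 1:5)
  expect_true(all(cc$rms$rms_eV == 0))
  expect_true(cc$converged)
  ## synthetic logistic decay is recovered
  t <- 2^(0:9)
  rms_true <- 0.002 + (0.25 - 0.002) / (1 + exp((log(t) - log(20)) / 0.5))
  series <- lapply(seq_along(t), function(i) {
    q <- pmf
    q$G_eV <- q$G_eV + rms_true[i]   # uniform offset => RMS = offset
    q
  })
  series[[length(series)]] <- pmf
  cc2 <- convergence_check(series, times = t, threshold = 0.01)
  expect_false(is.null(cc2$fit))
  cf <- coef(cc2$fit)
  expect_equal(unname(exp(cf["m"])), 20, tolerance = 0.05 * 20)
  ## monotonically growing differences: not converged
  grow <- lapply(1:5, function(i) { q <- pmf; q$G_eV <- q$G_eV + 0.05 * (5 - i); q })
  cc3 <- convergence_check(grow, times = 1:5, threshold = 0.01)
  expect_false(cc3$converged)
})
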