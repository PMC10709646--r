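## a smooth synthetic profile through prescribed stationary values
synth_profile <- function(pts) {
  sp <- splinefun(pts$x, pts$G, method = "natural")
  x <- seq(0, 1, length.out = 201)
  data.frame(x = x, G_eV = sp(x))
}

test_that("hand-built profiles decompose into the expected transition stats", {
  ## minima at 0 and 0.5 eV, single maximum at 0.7 eV
  prof <- synth_profile(data.frame(x = c(0, 0.2, 0.45, 0.72, 0.90, 1),
                                   G = c(0, 0.25, 0.70, 0.55, 0.50, 0.55)))
  rp <- analyze_profile(prof, smooth = 3)
  tr <- rp$transitions
  ov <- tr[tr$transition == "GC->GstarCstar", ]
  ## oracle: the curve's own barrier top and product minimum
  fwd_true <- max(prof$G_eV)
  rxn_true <- min(prof$G_eV[prof$x > 0.6])
  expect_lt(abs(ov$dG_rxn_eV - rxn_true), 0.01)
  expect_lt(abs(ov$dG_fwd_eV - fwd_true), 0.01)
  expect_lt(abs(ov$dG_rev_eV - (fwd_true - rxn_true)), 0.01)
  ## strictly monotone profile: overall rise only, no intermediates
  mono <- data.frame(x = seq(0, 1, length.out = 101),
                     G_eV = 1.3 * seq(0, 1, length.out = 101)^1.5)
  rm_ <- analyze_profile(mono)
  expect_equal(nrow(rm_$stationary), 2L)
  expect_equal(rm_$transitions$dG_rxn_eV, 1.3, tolerance = 0.02)
  expect_true(is.na(rm_$transitions$dG_rev_eV))
})

test_that("a three-well profile yields stepwise transitions with consistent barriers", {
  prof <- synth_profile(data.frame(
    x = c(0, 0.25, 0.5, 0.62, 0.75, 1),
    G = c(0, 0.60, 0.55, 0.70, 0.65, 0.80)))
  rp <- analyze_profile(prof, smooth = 3)
  tr <- rp$transitions
  s1 <- tr[tr$transition == "GC->G_minus_C_plus", ]
  expect_equal(s1$dG_fwd_eV - s1$dG_rev_eV, s1$dG_rxn_eV, tolerance = 0.01)
  ## sequential thermodynamic consistency: energies add, K's multiply
  s2 <- tr[tr$transition == "G_minus_C_plus->GstarCstar", ]
  ov <- tr[tr$transition == "GC->GstarCstar", ]
  expect_equal(s1$dG_rxn_eV + s2$dG_rxn_eV, ov$dG_rxn_eV, tolerance = 1e-10)
  expect_equal(s1$K * s2$K, ov$K, tolerance = 1e-10)
})

test_that("equilibrium constants reproduce the printed magnitudes", {
  expect_equal(equilibrium_constant(0, 310), 1)
  ## 0.60 eV at 310 K: printed 1.68e-10 (rounded dG), agree within ~10%
  expect_equal(equilibrium_constant(0.60, 310) / 1.68e-10, 1,
               tolerance = 0.1)
  expect_equal(round(log10(equilibrium_constant(1.35, 310))), -22)
  expect_equal(round(log10(equilibrium_constant(0.43, 310))), -7)
})

test_that("reverse-barrier fractions count exactly", {
  with_rev <- analyze_profile(synth_profile(data.frame(
    x = c(0, 0.25, 0.5, 0.62, 0.75, 1),
    G = c(0, 0.60, 0.55, 0.70, 0.65, 0.80))), smooth = 3)
  without <- analyze_profile(data.frame(x = seq(0, 1, length.out = 101),
                                        G_eV = seq(0, 1, length.out = 101)))
  ens <- c(rep(list(with_rev), 42), rep(list(without), 58))
  expect_equal(reverse_barrier_fraction(ens, "GC->G_minus_C_plus"), 42)
  expect_equal(reverse_barrier_fraction(rep(list(without), 10),
                                        "GC->G_minus_C_plus") %in% NA, TRUE)
  expect_warning(reverse_barrier_fraction(rep(list(without), 10),
                                          "GC->G_minus_C_plus"), "undefined")
  expect_equal(reverse_barrier_fraction(rep(list(with_rev), 5),
                                        "GC->G_minus_C_plus"), 100)
  all_absent <- c(rep(list(with_rev), 3))
  all_absent[[1]]$transitions$dG_rev_eV <- NA
  all_absent[[2]]$transitions$dG_rev_eV <- NA
  all_absent[[3]]$transitions$dG_rev_eV <- NA
  expect_equal(reverse_barrier_fraction(all_absent, "GC->G_minus_C_plus"), 0)
})

test_that("percent-change conventions reproduce the printed comparisons", {
  expect_equal(percent_reduction(1.68, 1.18), 29.76, tolerance = 0.01)
  expect_equal(percent_relative_increase(42, 68), 61.90, tolerance = 0.01)
  expect_error(percent_reduction(0, 1), "zero")
  a <- analyze_profile(synth_profile(data.frame(
    x = c(0, 0.25, 0.5, 0.62, 0.75, 1),
    G = c(0, 0.60, 0.55, 0.70, 0.65, 0.80))), smooth = 3)
  cmp <- compare_profiles(a, a)
  expect_true(all(abs(cmp$reduction_pct) < 1e-10))
  expect_true(all(abs(cmp$relative_increase_pct) < 1e-10))
})

test_that("decay trajectories classify by the separatrix crossing region", {
  geom <- geometry_refs()
  mk <- function(upath) {
    r1 <- geom$r_cov + upath[, 1] * (geom$R_NN - 2 * geom$r_cov)
    r2 <- geom$r_cov + upath[, 2] * (geom$R_ON - 2 * geom$r_cov)
    structure(data.frame(t_fs = seq_along(r1), r1_A = r1, r2_A = r2,
                         lambda = lambda_of(r1, r2, geom)),
              class = c("dpt_trajectory", "data.frame"))
  }
  ## via the G-C+ corner (central proton returns last)
  u_zw <- cbind(c(1, 1, 1, 0.6, 0.2, 0.05), c(1, 0.6, 0.1, 0.05, 0.05, 0.05))
  expect_equal(classify_decay(mk(u_zw))$class, "via G-C+")
  u_zw2 <- cbind(c(1, 0.6, 0.1, 0.05, 0.05), c(1, 1, 1, 0.6, 0.05))
  expect_equal(classify_decay(mk(u_zw2))$class, "via G+C-")
  ## straight diagonal crossing
  u_sync <- cbind(seq(1, 0.02, length.out = 20),
                  seq(1, 0.02, length.out = 20))
  cd <- classify_decay(mk(u_sync))
  expect_equal(cd$class, "synchronous/near-maximum")
  expect_true(cd$decayed)
  ## non-decayed trajectory: class none, time undefined
  u_stay <- cbind(rep(0.95, 5), rep(0.95, 5))
  cd0 <- classify_decay(mk(u_stay))
  expect_false(cd0$decayed)
  expect_equal(cd0$class, "none")
  expect_error(classify_decay(mk(cbind(0.1, 0.1))), "basin")
})

test_that("separation trends fit exactly linear feature energies", {
  ## synthetic MEP results with linear feature shifts
  geom <- geometry_refs()
  mk_mep <- function(s) {
    t <- seq(0, 1, length.out = 21)
    img <- cbind(1.03 + t * 0.87, 1.03)
    img <- rbind(img, cbind(1.90, 1.03 + t[-1] * 0.89))
    E <- c(seq(0, 0.6, length.out = 21), seq(0.6, 1.1, length.out = 20)) +
      s * 0.5
    E[1] <- 0  # GC reference unaffected by s
    structure(list(images = img, energy = E,
                   arc = c(0, cumsum(sqrt(rowSums(diff(img)^2)))),
                   via = "G_minus_C_plus",
                   saddles = data.frame(r1 = c(1.465, 1.90),
                                        r2 = c(1.03, 1.475),
                                        energy_eV = c(0.6 + 0.9 * s,
                                                      1.2 + 0.7 * s),
                                        grad_norm = 1e-9),
                   n_images = nrow(img), s = s),
              class = "dpt_mep")
  }
  meps <- lapply(c(0, 0.23, 0.6), mk_mep)
  tr <- separation_trend(meps)
  f <- tr$fits
  expect_equal(f$slope[f$feature == "TS1"], 0.9, tolerance = 1e-8)
  expect_equal(f$slope[f$feature == "TS2"], 0.7, tolerance = 1e-8)
  expect_lt(max(f$slope_se), 1e-8)
  ## two separations only: refuses to fit
  expect_message(t2 <- separation_trend(meps[1:2]), "refusing")
  expect_null(t2$fits)
})

test_that("calibrated separation scans raise TS1, TS2 and the zwitterion", {
  p <- calib("helicaseN_frozen")
  meps <- lapply(c(0, 0.23, 0.6), function(sv) {
    mn <- find_minima(p, s = sv)
    neb_path(p, min_pos(mn, "GC"), min_pos(mn, "GstarCstar"), s = sv)
  })
  tr <- separation_trend(meps, c(0, 0.23, 0.6))
  f <- tr$fits
  for (ft in c("TS1", "TS2", "zwitterion"))
    expect_gt(f$slope[f$feature == ft], 0)
})
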