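# gcdpt

Double proton transfer (DPT) energetics in guanine-cytosine base pairs,
at desk scale.

A GC base pair can tautomerise to G\*C\* when its two hydrogen-bond
protons hop across: the central N1(G)-H···N3(C) proton and the outer
N4(C)-H···O6(G) proton. The tautomer mimics Watson-Crick geometry and can
template point mutations at replication. The energetics of this reaction
differ sharply between aqueous duplex DNA, the last base pair (N) at the
PcrA helicase single-stranded-DNA binding site, and the helicase's N624A
mutant — and between the *thermal* (equilibrium free energy) and
*frozen* (instantaneous potential-energy) descriptions of the transfer.

`gcdpt` re-creates that analysis chain on analytic 2D model potentials
over the two proton coordinates, calibrated to published stationary-point
energy tables for seven scenarios. On these surfaces the package provides:

* **surfaces** — Gaussian wells/ramps/bumps on a confined background with
  compression walls and separation coupling; least-squares calibration to
  a stationary table (`calibrate_surface`, `stationary_table`);
* **dynamics** — BAOAB Langevin integration (compiled core) with the
  4-distance umbrella restraint, steered base-pair separation, and
  unbiased tautomer-decay runs (`simulate_dpt`, `run_umbrella_series`,
  `steered_separation`, `decay_run`);
* **WHAM** — a from-scratch binless weighted-histogram estimator with
  exact per-frame restraint energies, block-bootstrap uncertainties and a
  logistic sampling-time convergence diagnostic (`wham_pmf`,
  `bootstrap_pmfs`, `convergence_check`), plus the exact quadrature
  marginal for validation (`boltzmann_marginal`);
* **frozen-surface workflow** — energy grids, node-exact smooth
  interpolation, quasi-Newton minima, climbing-image nudged-elastic-band
  paths (`sample_grid`, `interpolate_grid`, `find_minima`, `neb_path`);
* **statistics** — per-transition reaction energies, barriers and
  equilibrium constants, reverse-barrier frequencies, mutant
  comparisons, decay classification and separation trends
  (`analyze_profile`, `equilibrium_constant`, `reverse_barrier_fraction`,
  `compare_profiles`, `classify_decay`, `separation_trend`);
* **orchestration** — an end-to-end scenario runner with seeded
  reproducibility and typed file formats (`run_scenario`, `write_pmf`,
  `write_grid`, `write_report`, ...).

The collective coordinate is λ, the average relative change of the four
hydrogen-bond distances from the canonical geometry (0 at GC, 1 at
G\*C\*, 1/2 at either single-transfer zwitterion). Transition statistics
follow the standard conventions: ΔG_rxn = G(product) − G(reactant),
ΔG_fwd/ΔG_rev barriers against the intervening saddle, and
K = exp(−ΔG_rxn / k_B T) at T = 310 K.

## Worked example

Calibrate the frozen helicase-N surface, locate its minima through the
grid pipeline, and pull the reaction profile off the minimum-energy path:

```r
library(gcdpt)

surf <- calibrate_surface(stationary_table("helicaseN_frozen"))
mins <- find_minima(interpolate_grid(sample_grid(surf, 33)))
mins
#>            state     r1     r2 energy_eV grad_norm
#> 1             GC 0.9694 0.9573 -0.007092 5.688e-09
#> 2 G_minus_C_plus 1.8845 0.9495  1.352420 3.876e-08
#> 4     GstarCstar 2.0549 2.0643  1.780140 2.089e-08
#> 3 G_plus_C_minus 0.9527 1.9894  1.930578 4.499e-10

mep <- neb_path(surf,
                unlist(mins[mins$state == "GC", c("r1", "r2")]),
                unlist(mins[mins$state == "GstarCstar", c("r1", "r2")]),
                via = "G_minus_C_plus")
analyze_profile(mep, scenario = "helicaseN_frozen")$transitions
#>                   transition dG_rxn_eV dG_fwd_eV dG_rev_eV        K
#> 1         GC->G_minus_C_plus     1.350      1.38     0.029 1.12e-22
#> 2 G_minus_C_plus->GstarCstar     0.429      1.41     0.980 1.06e-07
#> 3             GC->GstarCstar     1.779        NA        NA 1.19e-29
```

Reading: on the frozen (instantaneous) helicase-N landscape the protons
must gain 1.35 eV to reach the G⁻C⁺ zwitterion (forward barrier 1.38 eV)
and a further 0.43 eV to the G\*C\* tautomer; the corresponding Boltzmann
factors at 310 K (~10⁻²² and ~10⁻⁷) are why near-instantaneous transfer
into the tautomer is strongly suppressed at this site. (Interpolant
minima energies are absolute surface values, here with GC ≈ 0 by the
calibration convention; profile energies are always referenced to
GC = 0. The grid interpolant places the GC minimum within 0.01 eV of the
analytic zero.)

The thermal counterpart (umbrella sampling → WHAM) of the same question:

```r
surf_t <- calibrate_surface(stationary_table("helicaseN_thermal"))
trajs  <- run_umbrella_series(surf_t, simulation_settings(seed = 1))
pmf    <- wham_pmf(trajs)
analyze_profile(pmf, scenario = "helicaseN_thermal")
```

A full scenario (calibration, umbrella series, WHAM + bootstrap, frozen
pipeline, decay, separation scan) runs from one seeded config:

```r
rep <- run_scenario(scenario_config("helicaseN_thermal",
                                    frozen_scenario = "helicaseN_frozen",
                                    out_dir = "out/helicaseN", seed = 1))
```

## Package layout

```
R/                 surfaces, coordinates, Langevin driver, WHAM, MEP,
                   profiles, I/O, scenario runner
src/               BAOAB Langevin core (Rcpp)
inst/extdata/      packaged stationary-point calibration tables (CSV)
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (model, assumptions, limitations)
scripts/           acceptance script
```

See `vignettes/dpt-methods.Rmd` for the model's assumptions, the
numerical choices, and its known limitations.
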