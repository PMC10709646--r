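---
title: "Modelling double proton transfer energetics in GC base pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling double proton transfer energetics in GC base pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdpt)
```

## The problem

A guanine-cytosine base pair can convert to its rare imino-enol tautomer
G\*C\* by a double proton transfer (DPT): the central N1(G)-H...N3(C)
proton and the outer N4(C)-H...O6(G) proton both hop across their
hydrogen bonds. The tautomer mimics Watson-Crick geometry and, if it
survives strand separation, templates G-T and A-C mismatches — a route to
spontaneous point mutations. The energetics of this reaction change
dramatically between aqueous duplex DNA and the last base pair (N) at the
single-stranded-DNA binding site of PcrA helicase, and again when the
nearby asparagine N624 is mutated to alanine.

`gcdpt` studies this system at desk scale. All quantum-chemical detail is
replaced by analytic two-dimensional model potentials over the two proton
coordinates `(r1, r2)`, calibrated so that their stationary-point energies
reproduce published free-energy (umbrella-sampling) and frozen-surface
(minimum-energy-path) tables for seven scenarios. Everything downstream —
umbrella sampling, WHAM, bootstrap errors, NEB paths, tautomer decay,
separation scans — operates on these calibrated surfaces, where every
claim is checkable against quadrature or enumeration.

## Coordinates

Both hydrogen bonds are treated as collinear, so each proton position is
one number: its distance `r` from the covalent donor, sampled on
[0.9, 2.5] Å. `r ≈ 1.03` Å means the proton is bonded to its donor;
`r ≈ R − 1.03` (with donor-acceptor lengths `R_NN = 2.93`,
`R_ON = 2.95` Å) means it has transferred. The four distance reaction
coordinates are the donor-H and H-acceptor distances of the two bonds;
the collective coordinate λ is their average relative change from the
canonical references, so λ = 0 at GC and λ = 1 at G\*C\*, and both
single-transfer zwitterions (G⁻C⁺, G⁺C⁻) sit at λ = 1/2. Because the two
asynchronous pathways share their λ level sets, profiles are always
reported per pathway (binned within a 0.35 Å tube around the pathway), as
the published per-pathway PMFs are.

The donor-acceptor lengths and the 1.03 Å covalent distance are standard
N-H/O...N geometry; the source tables print no geometric values, so these
are configurable constants of `geometry_refs()`.

## The model surface

`surface_params()` builds, and `calibrate_surface()` fits, a sum of smooth
terms:

* one isotropic Gaussian **well** per chemical state present in a
  scenario (GC always; zwitterions/tautomer when the table lists them);
* one broad Gaussian **ramp** per non-reference minimum, whose fitted
  amplitude sets that state's energy relative to GC — this is the
  "environmental destabilisation" knob;
* one Gaussian **bump** per transition state, whose signed amplitude sets
  the saddle energy;
* a central **synchronous-ridge** bump: moving both protons at once costs
  extra energy, keeping the synchronous diagonal above the asynchronous
  corner routes, as the published synchronous-vs-asynchronous barrier
  ordering requires;
* a weak quadratic confinement plus **cubic-hinge compression walls** on
  both sides of each coordinate (a proton squeezed into its acceptor or
  its donor is strongly repelled). The walls matter twice: they close
  unphysical low-energy detours around the fitted saddles (without them
  the 2.76 eV frozen helicase-N barrier cannot be imposed), and they keep
  every stationary feature inside the sampled 0.9-2.5 Å domain. Cubic
  hinges are C²-smooth with zero fourth derivative, so grid interpolation
  stays accurate across them;
* **separation coupling**: an additive term `s · g(r1, r2)` with positive
  Gaussians over TS1, TS2 and the G⁻C⁺ region, so that mechanical
  base-pair opening `s` raises the transition states and the zwitterion
  roughly linearly while leaving GC and G\*C\* nearly untouched — the
  qualitative pattern reported for steered separation scans.

Two fixed shape sets exist (`surface_shape()`): *thermal* surfaces use
soft, broad features because they are umbrella-sampled — the magnitude of
the negative curvature along the transfer path must stay comparable to
the combined restraint stiffness (2k ≈ 4.15 eV/Å²) or no window ladder
can cover the path; *frozen* surfaces carry the sharper instantaneous
barriers and are only probed by grid/NEB/decay operations, so they use
stiffer wells. Both sets were fixed once, during design, and are not
per-scenario tuning knobs.

Calibration measures the surface's actual stationary points at every
step: minima by damped-descent + BFGS from the state positions, saddles
by a dynamic-programming minimax seed between the adjacent minima
followed by eigenvector-following refinement. Since the stationary
energies are linear in the amplitudes at fixed positions, a damped
fixed-point iteration on the exact linear system supplies the starting
vector; a Nelder-Mead least-squares polish (iteration cap 5000) finishes
the fit, and is skipped when the linear solution is already at numerical
resolution. Any residual above the table tolerance (default 0.02 eV)
aborts with the residual vector. A fitted feature must be a true
minimum/index-1 saddle, must stay within 0.45 Å of its reference
position, and must lie inside the sampled domain.

The thermal tables deliberately carry no TS2 row except for helicase-N
(where the printed step-2 forward barrier equals the step-2 reaction
energy, pinning TS2 at the tautomer energy, i.e. barrier-less — which the
sub-picosecond decay behaviour requires). For the other thermal
scenarios the saddle between the zwitterion and tautomer wells is left
uncalibrated and sits ~0.2 eV above G\*C\*; thermal step-2 reverse
barriers are therefore overestimated by the model. No reported quantity
depends on them, but profiles of thermal surfaces should be read with
this limitation in mind. One known table discrepancy: the source's
running text gives the aqueous GC → G\*C\* asymmetry as 0.54 ± 0.08 eV
while its table prints 0.60 ± 0.05; the packaged tables follow the table.

## Langevin dynamics (the synthetic-data generator)

`simulate_dpt()` integrates underdamped Langevin dynamics with the BAOAB
splitting (exact Ornstein-Uhlenbeck step) at `T = 310` K, `dt = 0.5` fs,
friction `γ = 5` ps⁻¹ and effective mass 1 amu per proton coordinate,
with reflective walls at the domain edges. The friction is the one free
kinetic parameter: the model declares it once, at a value for which the
helicase-N tautomer decays within the reported 0.6 ps. Umbrella windows
restrain all four distances with the conventional force constant
20000 kJ/mol/nm² (2.07 eV/Å² per distance).

`run_umbrella_series()` places 64 windows at evenly spaced λ over
[−0.1, 1.1] along the chosen pathway and runs 7 replicas of 8 ps per
window, discarding a 2 ps burn-in. Replica initial states are drawn from
the restrained Boltzmann density by quadrature ("boltzmann" start mode):
the published analysis assumes fully equilibrated windows, and for the
helicase-class barriers the in-window relaxation between restraint
sub-basins is astronomically slower than any affordable window length,
so equilibrated starts are the only honest way to emulate equilibrated
data. Window counts and replica numbers are the package's own defaults
(the source states only "at least 8 ps per replica per window").

What the generator deliberately does **not** emulate: explicit solvent
and protein atoms, coupling between the proton coordinates and all other
degrees of freedom (beyond the friction bath), nuclear quantum effects,
and snapshot-to-snapshot diversity of the frozen surfaces (we have one
calibrated surface per scenario, not seven replicas). Passing tests
therefore validate the estimators and the calibrated model, not the
underlying electronic structure.

## WHAM

`wham_pmf()` implements the binless weighted-histogram estimator: every
frame carries its exact four-distance restraint energy under every
window, and the window free-energy constants are iterated to
self-consistency until the largest change of the unitless log-weight
falls below 1e-6. Frames are aggregated on a 0.005 Å position grid
(mathematically identical to per-frame weights; the restraint is
evaluated at each cell's occupancy centroid). Two variance guards are
built in: positions visited fewer than 3 times are excluded from the
*profile* (an isolated far-tail frame carries an unbounded importance
ratio), and the profile is binned within the pathway tube. Bins never
sampled are NA, never interpolated. `bootstrap_pmfs()` re-solves WHAM on
100 block-bootstrap resamples (50 fs blocks, exceeding the velocity
autocorrelation time at the default friction) for per-bin uncertainties;
whether the source bootstraps frames, blocks or replicas is not stated —
block bootstrap is our choice. `convergence_check()` fits the
four-parameter logistic in log-time to the RMS difference against the
longest-time profile, falling back to a threshold-only criterion if the
fit fails.

A known, quantified limitation: with the published restraint stiffness,
surfaces whose first barrier exceeds ~1 eV (helicase-N) have a band of
the path with negative curvature stronger than the restraint. No window
has a stable mean position there, the band is informationally starved,
and the window constants accumulate a coherent few×0.01 eV offset across
it. The package reports what the method can honestly deliver; the
quadrature marginal (`boltzmann_marginal()`) is the exact reference for
every comparison. This mirrors the large published uncertainties
(±0.07-0.13 eV) for exactly those profiles.

## Frozen-surface workflow

`sample_grid()` evaluates a scenario surface on a 33×33 grid (0.05 Å
spacing — interpolation error is then an order of magnitude below the
smallest printed barrier differences); `interpolate_grid()` builds a
tensor-product natural cubic spline (node-exact, smooth, restricted to
the hull); `find_minima()` runs damped quasi-Newton descents from the
four quadrant centres, merges duplicates within 0.02 Å, labels minima by
quadrant, and requires gradient norms below 1e-4 eV/Å. `neb_path()`
relaxes a 32-image nudged elastic band (improved tangent, spring constant
1 eV/Å²) by damped projected descent to a 5e-3 eV/Å force tolerance; the
climbing image is then converged onto the exact saddle by
eigenvector-following. Initial paths route through a chosen zwitterion
corner; `via = "auto"` relaxes both and returns the lower barrier, since
a minority of published replicas route via G⁺C⁻.

## Decay and separation

`decay_run()` places the frozen-surface tautomer product on a thermal
surface and integrates unbiased dynamics until the GC basin (λ < 0.15) or
a 2 ps cap; `classify_decay()` assigns each decayed replica to
"via G-C+", "via G+C-" or "synchronous/near-maximum" by the nearest
landmark when the trajectory first crosses the separatrix u₁ + u₂ = 1.
`steered_separation()` imposes a monotone separation schedule (or an
overdamped constant-force pull); `separation_trend()` fits per-feature
lines against s and reports the Pearson correlation of the overall
asymmetry with s. The published "constant separating force
(500 kJ/mol/nm²)" mixes force and stiffness units; we implement the
schedule as primary and a constant-force mode with a declared mobility.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| λ bins | 120 over [−0.1, 1.1] | resolves ~0.05-wide barriers without empty interior bins |
| WHAM tolerance | 1e-6 (log-weight) | published tolerance |
| Bootstrap | 100 samples, 50 fs blocks | published count; blocks beat the velocity autocorrelation |
| Reverse-barrier detection | 0.005 eV | above WHAM discretisation noise |
| Basin cutoffs | λ < 0.15 (GC), λ > 0.85 (G\*C\*) | between the wells and the λ = 1/2 zwitterions |
| Stationarity | grad norm < 1e-4 eV/Å | defines "stationary" throughout |
| NEB | 32 images, k = 1 eV/Å², tol 5e-3 eV/Å | doubling images moves barriers < 0.005 eV |
| Grid | 33×33 (0.05 Å) | interpolation error ≪ barrier differences |
| Umbrella defaults | 64 windows × 7 replicas × 8 ps | coverage at the published restraint stiffness |

Problem sizes in the test-suite runs are scaled-down versions of these
defaults (fewer windows/replicas/steps) chosen so each property remains
decidable; the defaults above are what `run_scenario()` uses.

## A worked chain

```{r, eval = FALSE}
surf <- calibrate_surface(stationary_table("helicaseN_frozen"))
grid <- sample_grid(surf, 33)
mins <- find_minima(interpolate_grid(grid))
mep  <- neb_path(surf, unlist(mins[mins$state == "GC", c("r1", "r2")]),
                 unlist(mins[mins$state == "GstarCstar", c("r1", "r2")]))
analyze_profile(mep, scenario = "helicaseN_frozen")
```

## Known limitations

* One calibrated surface per scenario: printed replica-ensemble spreads
  (e.g. "five of seven replicas") depend on snapshot diversity the model
  does not carry.
* Thermal surfaces overestimate step-2 reverse barriers except where the
  tables pin TS2 (see above); duplex thermal tautomer decay is therefore
  slower in the model than the published sub-picosecond lifetime.
* The WHAM-vs-quadrature agreement degrades to a few×0.01 eV on the
  helicase-N thermal surface for the structural reason quantified above.
* No electronic structure, no hydration analysis, no tunnelling rates:
  out of scope by design.
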