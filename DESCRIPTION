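Package: gcdpt
Title: Double Proton Transfer Energetics in Guanine-Cytosine Base Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale free-energy analysis of the double proton transfer
    (DPT) that converts a canonical guanine-cytosine base pair into its
    G*C* tautomer, in aqueous duplex DNA and at the single-stranded DNA
    binding site of PcrA helicase (wild type and N624A mutant). Provides
    analytic two-dimensional model potentials over the two proton
    coordinates calibrated to stationary-point energy tables, Langevin
    dynamics with umbrella restraints on the four hydrogen-bond distances,
    a from-scratch weighted-histogram (WHAM) estimator with block-bootstrap
    uncertainty and a logistic convergence diagnostic, the frozen
    ("instantaneous") potential-energy-surface workflow (energy grids,
    C1-smooth interpolation, quasi-Newton minima, nudged-elastic-band
    minimum energy paths), tautomer-decay simulation and classification,
    and base-pair separation scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
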