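Package: ksnet
Title: Keller-Segel Modeling of Brain Microvascular Network Formation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying a modified Keller-Segel chemotaxis model of
    brain microvascular endothelial cell (BMEC) pattern formation. Provides a
    finite-difference forward simulator on zero-flux (Neumann) grids with a
    bistable cubic reaction term, reproducing the gamma-dependent pattern
    regimes (homogeneous, invasion wave, network, degenerate network); an
    elliptic inverse solver that reconstructs the chemoattractant field from
    consecutive cell-density frames by a restarted GMRES Krylov iteration; a
    reduced four-dimensional coupled ODE model with complete equilibrium
    enumeration via a scalar fixed-point map, stability classification and a
    bifurcation scan in the chemotactic sensitivity; point-trace extraction
    with three-phase changepoint segmentation; and a synthetic fixture
    generator plus command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
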