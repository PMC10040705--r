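Package: cavsep
Title: Cavity-Method Phase Diagrams for Lattice Models of Biomolecular
    Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling liquid-liquid phase separation in binary and
    ternary lattice solution models (generalized Potts models with solvent).
    Computes phase diagrams from microscopic couplings via the Bethe-Peierls
    (cavity) approximation: exact message passing on trees, homogeneous
    fixed points, analytic binary spinodals, ternary stability maps via the
    Routh-Hurwitz criterion, and Maxwell-construction binodals, alongside
    regular-solution (Curie-Weiss) baselines.  Includes Kawasaki (conserved
    composition) Monte Carlo simulation of the lattice model with annealing
    schedules and specific-heat critical-point estimation, an automated
    detector of phase separation from lattice snapshots based on local
    density convolution and free-energy-profile bimodality, and inverse
    modeling of binary-labeled phase diagrams by differential evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
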