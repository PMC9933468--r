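Package: rodlattice
Title: Ground States and Monte Carlo Stability of Screened Charged-Rod
    Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained modelling of suspensions of like-charged rigid
    rods interacting through a far-field anisotropic screened-Coulomb
    (Yukawa) pair potential. Builds stacked hexagonal crystals
    (AAA/ABA/ABC) with heliconical orientation fields, locates ground
    states and metastable minima by lattice-parameter and tilt-angle
    scans, runs zero- and finite-temperature Metropolis Monte Carlo with
    adaptive single-rod moves and isochoric box moves, computes nematic
    order parameters and pair correlations, and maps reduced state points
    onto cellulose-nanocrystal suspension conditions (evaporation curves,
    pH, line valencies, effective aspect ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
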