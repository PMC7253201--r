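Package: relchron
Title: Substitution-Model Complexity and Relative Divergence-Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for asking whether simple
    nucleotide substitution models (Jukes-Cantor) yield divergence-time
    estimates equivalent to complex models (GTR with gamma rate variation).
    Simulates clocklike sequence evolution on timetrees under GTR+Gamma,
    estimates pairwise distances with closed-form multiple-hit corrections
    (JC, K2, TN, with optional gamma), computes Felsenstein-pruning
    log-likelihoods and maximum-likelihood branch lengths on fixed
    topologies across a model ladder, dates trees with a calibration-free
    relative-rate recursion, and compares estimate sets with
    through-origin regression, mean relative absolute error, stratified
    slopes, and interval-overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Matrix,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
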