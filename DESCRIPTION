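Package: fret3cw
Title: Photon-by-Photon Maximum Likelihood Analysis of Fast Three-Color
    Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical inference for three-color single-molecule FRET
    measured under continuous-wave donor excitation.  Builds continuous-time
    Markov kinetic models of protein folding and binding, including acceptor
    photoblinking and photobleaching states, and evaluates the photon-by-photon
    likelihood of trajectories of arrival times and detection channels via
    spectral propagators.  Provides Nelder-Mead maximum-likelihood fitting with
    curvature-based uncertainties and BIC model comparison, correction of
    acceptor count fractions for background, spectral cross-talk and direct
    acceptor excitation, conversion between acceptor fractions and the three
    FRET efficiencies, Gaussian-chain averaging of efficiencies over
    fluctuating inter-dye distances, photon-level Viterbi state assignment,
    cross-correlation analysis, and a seeded photon simulator and recoloring
    engine for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
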