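Package: ipdpop
Title: Population Games, Zero-Determinant Strategies and Information
    Players for the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of cooperation in well-mixed
    populations playing the iterated Prisoner's Dilemma. Provides exact
    stationary-score analysis of memory-one strategies via the Press-Dyson
    determinant, zero-determinant (ZD) strategy construction,
    frequency-dependent fitness-difference analysis, an "information player"
    that infers opponent strategies and population composition from the
    history of play (Bayesian strategy estimation, information-gain move
    selection, self-recognition by binomial test and a two-state hidden
    Markov model, frequency-dependent strategy optimization), and a fast
    evolutionary simulation engine (imitation and Moran dynamics) producing
    fixation probabilities and identification ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cli,
    withr,
    optparse
Config/testthat/edition: 3
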