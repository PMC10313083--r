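Package: frsim
Title: Friendly Rivals and Evolutionary Dynamics in the Iterated Donation Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact long-term payoffs, cooperation levels and strategy
    classification for deterministic memory-(m1, m2) strategies of the
    iterated donation game under implementation errors, together with
    small-mutation-limit evolutionary Monte Carlo simulations for
    well-mixed and group-structured populations. Strategies are judged
    efficient by their stationary self-cooperation level and rival by
    negative-cycle detection (Floyd-Warshall) on a payoff-difference
    graph; friendly rivals are strategies that are both. Includes
    enumeration and census machinery for exact-memory strategy classes
    and a two-step mutant sampler over memory lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
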