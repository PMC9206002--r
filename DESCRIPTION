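Package: mgng
Title: Simulation and Computational Modelling of the Motivational Go/NoGo Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying Pavlovian/motivational biases in instrumental
    learning with the orthogonalized motivational Go/NoGo task. Simulates the
    task environment (balanced cue schedules, 80/20 probabilistic feedback),
    generates choices from a nested family of Rescorla-Wagner reinforcement
    learning models (feedback sensitivity, learning rate, Go bias, motivational
    bias, and a drug-split variant), fits the models to trial-level choice data
    by maximum a posteriori estimation with Laplace-approximate model evidence,
    performs random-effects Bayesian model selection (model frequencies,
    exceedance and protected exceedance probabilities, Bayes omnibus risk),
    and validates parameter and drug-effect recovery by simulate-and-refit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
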