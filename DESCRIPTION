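Package: pemod
Title: Reward Prediction-Error Signals, Life Stress, and Fluid Intelligence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a probabilistic reversal-learning task, fits
    Rescorla-Wagner/softmax reinforcement-learning models with hierarchical
    empirical-Bayes (expectation-maximization) priors, builds prediction-error
    modulated fMRI regressors convolved with a canonical hemodynamic response
    function, estimates per-subject BOLD prediction-error betas by ordinary
    least squares, and tests whether chronic life stress moderates the
    association between the striatal prediction-error signal and fluid
    intelligence via hierarchical (two-step) interaction regression. Includes
    a synthetic-cohort generator so the full analysis pipeline can be
    exercised and validated end to end by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
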