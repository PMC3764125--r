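Package: celdyn
Title: Mixed-Effects Discrete-Distribution Models for Monthly
    Contrast-Enhancing Lesion Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population (nonlinear mixed-effects) analysis of monthly
    contrast-enhancing-lesion counts in relapsing-remitting multiple
    sclerosis. Implements a ladder of discrete count distributions
    (Poisson, Poisson mixture, zero-inflated Poisson, generalized
    Poisson, negative binomial, zero-inflated negative binomial) with
    Markov lagged-count terms and a steroid-month covariate, log-normal
    inter-subject variability, Laplace-approximate marginal likelihood
    (with an adaptive Gauss-Hermite oracle), simulation-based predictive
    checks (numerical predictive checks, prediction intervals,
    variance-versus-mean diagnostics, external 6-month validation), a
    dose-randomization test for the steroid effect, and a synthetic
    cohort generator with relapse-triggered dosing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    glmmTMB
Config/testthat/edition: 3
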