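Package: clustercf
Title: Causal Forests Versus Propensity Weighting Under Cluster-Level
    Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo machinery for comparing causal forests and
    stabilized inverse-probability-of-treatment weighting (IPTW) when
    treatment allocation is driven by hospital- or surgeon-level
    covariates.  Provides a parametric clustered-data generator, a
    plasmode-style generator that resamples covariates from a base
    cohort, an honest double-sample causal forest with doubly robust
    (AIPW) average-treatment-effect estimation, a stabilized-weight
    IPTW estimator with a random-intercept logistic outcome model, and
    simulation-study performance metrics (relative bias, empirical
    standard error, coverage) with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
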