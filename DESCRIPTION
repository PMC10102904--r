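Package: crtmle
Title: Two-Stage Targeted Minimum Loss-Based Estimation for Cluster
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of intervention effects in cluster randomized
    trials when individual-level outcomes are differentially missing.
    Stage 1 estimates each cluster's endpoint with an individual-level
    TMLE that adjusts for baseline and post-baseline causes of outcome
    measurement (with empirical-mean, Kaplan-Meier, and ratio-endpoint
    variants); Stage 2 estimates the cluster-level treatment effect with
    a cluster-level TMLE using Adaptive Prespecification to select the
    adjustment set that minimizes the cross-validated influence-curve
    variance. Influence-curve-based inference on the risk-difference and
    risk-ratio scales supports both pair-matched and unmatched designs.
    Includes a trial simulator with counterfactual outcomes, unadjusted
    t-test and covariate-adjusted-residuals (CARE) comparators, and a
    benchmark runner reporting bias, coverage, and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
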