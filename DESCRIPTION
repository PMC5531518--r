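Package: pillrisk
Title: Resampling-Ensemble Risk Models for Venous Thromboembolism in
    Combined Oral Contraceptive Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates case-control risk prediction models for
    venous thromboembolism (VTE) among users of combined oral
    contraceptives. Implements a stability-selection style pipeline:
    repeated random half splits of the cohort, hot-deck imputation of
    missing genotypes and clinical covariates from control donor pools,
    stepwise logistic model selection under the Akaike Information
    Criterion on each training half, and aggregation of the replicate
    models into a final median-coefficient model with Wald inference and
    false-discovery-rate control. Out-of-sample performance is measured
    by the rank-based area under the ROC curve on the held-out halves,
    with a comparison harness for fixed published SNP panels and
    fixed-coefficient clinical scores. A synthetic-cohort generator draws
    genotypes under Hardy-Weinberg equilibrium and clinical covariates
    from specified distributions, providing ground truth for
    parameter-recovery and selection-stability checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
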