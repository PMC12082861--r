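Package: omicboost
Title: Multiomics Feature Selection, SMOTE Augmentation and Boosted
    Ensemble Classification for Binary Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting a binary clinical outcome (such as
    postoperative recurrence and metastasis) from multiomics cohorts.
    Implements statistical feature selection for discrete and continuous
    omics blocks (Fisher's exact, chi-square, pooled t, Mann-Whitney U and
    one-way ANOVA built from first principles), per-block principal
    component reduction into a unified design matrix, power-based sample
    size estimation, whole-dataset SMOTE augmentation scored by the maximum
    Fisher's discriminant ratio, and an AdaBoost ensemble of logistic,
    support-vector and naive-Bayes weak learners fused by a logistic
    stacking layer.  A seeded synthetic cohort generator emulates the
    statistical structure of a near-balanced multiomics study so that every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
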