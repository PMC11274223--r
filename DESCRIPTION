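Package: wivela
Title: Weighted Inheritance Voting Ensemble Learning for Imbalanced
    Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a weighted inheritance voting ensemble classifier
    for imbalanced multi-class tabular cohorts: a primary classifier's
    confident predictions are inherited directly, while uncertain samples
    are decided by weighted (soft or hard) voting over three base
    learners. Companion procedures cover a feature-importance
    threshold-sweep feature selector, cross-validated tuning of the
    confidence gate and voting weights, weighted aggregation of
    heterogeneous feature-importance scores, leakage-aware preprocessing
    (duplicate and out-of-range row removal, median imputation,
    standardization, SMOTE with optional undersampling), a repeated
    stratified cross-validation evaluation protocol, and a synthetic
    cohort generator emulating a small/appropriate/large-for-gestational-
    age obstetric study population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    randomForest,
    xgboost,
    e1071,
    rpart,
    caret,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
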