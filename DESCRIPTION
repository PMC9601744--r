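Package: cogprog
Title: Ranking Cognitive Assessment Items that Predict Alzheimer's Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying items of the 13-item Alzheimer's Disease
    Assessment Scale - Cognitive subscale (ADAS-Cog-13) that predict disease
    progression in longitudinal cohorts. Provides a synthetic ADNI-style cohort
    generator, visit-level integration of diagnosis and assessment tables,
    construction of a binary progression label from per-patient diagnosis
    trajectories, SMOTE minority oversampling, an ensemble feature-scoring
    stage (information gain, chi-squared, ReliefF) with min-max normalization,
    composite ranking with score-drop clustering, correlation-based redundancy
    filtering, derivation of reduced item subsets, and stratified
    cross-validated evaluation of the subsets with Bayesian, logistic and
    decision-tree classifiers reporting accuracy, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
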