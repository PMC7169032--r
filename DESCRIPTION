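Package: recruitcbr
Title: Case-Based Reasoning for Clinical-Study Recruitment from Coded EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks electronic-health-record registrants by likelihood of
    recruitment into a clinical study using case-based reasoning on coded
    clinical events (diagnoses, procedures, prescriptions, laboratory tests)
    held in long entity-attribute-value form. Known participants define a
    target profile of featured codes with central-tendency occurrence
    weights; every candidate is compared to the profile by per-entity cosine
    similarity, the four similarities are combined with weights fitted by
    linear regression, and the combined score is min-max scaled. Includes a
    two-fold cross-validation harness with ROC AUC (stratified bootstrap
    confidence intervals, sensitivity+specificity cut-off sweep), ranking
    metrics (precision at k, mean average precision, mean reciprocal rank)
    with best-possible and random-list reference values, overlap of the top
    of the ranking with a database-query candidate set, and a synthetic
    cohort generator that emulates sparse, heavy-tailed coded EHR data for
    testing the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    Matrix,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
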