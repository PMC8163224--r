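Package: dcvmir
Title: Biofluid miRNA Panel Analysis for Delayed Cerebral Vasospasm Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a 47-miRNA RT-qPCR biomarker panel measured
    in cerebrospinal fluid and plasma of aneurysmal subarachnoid hemorrhage
    patients, aimed at predicting delayed cerebral vasospasm (DCV) risk before
    onset. Implements relative-threshold-cycle (Crt) quality filtering with
    detection-limit censoring, global-mean delta-Crt normalization,
    per-miRNA differential-expression screening, empirical ROC analysis with
    perfect-discriminator selection, single-miRNA cutoff predictors, a
    Gini-impurity CART decision tree, and a majority-vote consensus
    classifier, together with a synthetic-cohort generator that emulates the
    statistical structure of such studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
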