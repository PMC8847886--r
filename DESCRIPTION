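Package: pnaxis
Title: Canonical Correlation Analysis of Brain Connectomes and Subject
    Measures with Family-Structured Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying the positive-negative mode of
    covariation between resting-state functional connectomes and behavioural,
    cognitive and demographic subject measures in family-structured cohorts
    (twins, siblings, singletons). Implements motion-based subject and run
    quality control with framewise-displacement censoring, ridge-regularized
    partial-correlation network matrices, subject-measure filtering with
    rank-based inverse normal transformation, confound construction and
    regression, covariance completion under missing data via
    nearest-positive-definite projection, PCA reduction, canonical correlation
    analysis with restricted permutation inference respecting
    monozygotic/dizygotic twin and sibling exchangeability blocks,
    variance-explained statistics, positive-negative axis and edge-level post
    hoc analyses, Ward clustering of group networks, and family-respecting
    train/test cross-validation. A synthetic cohort generator with a planted
    low-rank cross-view mode provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
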