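Package: socialconcord
Title: Concordance of Machine and Human Social Annotations at Rating,
    Structural, and Neural Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking automated (machine) annotators of social
    features in naturalistic stimuli against pools of human raters. Implements
    per-feature rating agreement with single-rater (leave-one-out intersubject
    consistency) and split-group reliability benchmarks, Fisher-z comparisons,
    representational-structure comparison of feature correlation matrices via
    Mantel permutation tests and principal coordinate analysis with loading
    concordance, and massive-univariate fMRI encoding-model comparison
    (canonical double-gamma HRF regressors, voxelwise OLS, group one-sample
    t-maps, Bonferroni family-wise-error thresholding, predictive values, and
    cumulative social-tuning maps). Includes seeded synthetic generators for
    rater pools, multi-round machine annotators with a low-end bias, and
    event-related BOLD data with known ground truth, so the full pipeline is
    testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
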