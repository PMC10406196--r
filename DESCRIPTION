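Package: cttrack
Title: Canonical Template Tracking for Multivariate Neural Pattern Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates condition-specific canonical activity-pattern
    templates from independent functional-localizer data and quantifies
    their activation in main-task data. Provides pattern extraction
    (run-wise and trial-wise least-squares, univariate and multivariate
    noise normalization, supertrial averaging, temporal smoothing,
    principal-component reduction), template estimation over regions of
    interest and time windows, tracking metrics (Pearson and Fisher-z
    correlation, Euclidean and cross-validated distances, cross-validated
    Mahalanobis distance, multiple regression and semi-partial
    correlations, shrinkage linear-discriminant decision values),
    searchlight and temporal-generalization mapping, nonparametric group
    inference (exact Wilcoxon signed-rank, permutation nulls,
    cluster-based family-wise-error and false-discovery-rate correction),
    reliability diagnostics, and a seeded simulator with known ground
    truth for validation.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
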