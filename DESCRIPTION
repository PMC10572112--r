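Package: keyfluc
Title: Keystroke Dynamics Biomarkers for Parkinson's Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw press/release keystroke logs into digital
    biomarkers of Parkinson's disease. Extracts the four canonical typing
    latencies (hold, interkey, press, release), applies an interquartile-range
    outlier fence with negative-interval removal, and computes scale-free
    log-ratio fluctuation statistics per subject. Includes per-feature
    diagnostic screening (ROC curves, AUC with exact binomial confidence
    intervals, DeLong paired comparisons, maximal-Youden cutoffs), cohort-level
    group comparisons (Kruskal-Wallis with Tukey-type rank post hoc) and
    Spearman severity correlations, plus a seeded synthetic cohort generator
    calibrated to published control and patient typing profiles so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
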