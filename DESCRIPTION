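Package: labelboot
Title: Set-Valued Classification Uncertainty in Survival Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Propagates multiclass classification uncertainty into
    downstream survival estimation. Implements the least-ambiguous
    set-valued (LABEL) classifier with split conformal calibration and
    class-specific coverage targets, a weighted-labeling bootstrap that
    draws one label per resampled observation from its conformal label
    set, naive argmax comparators, one-vs-rest classification metrics,
    and stratified Kaplan-Meier survival summaries with Greenwood
    confidence intervals. Includes a calibrated synthetic-data generator
    emulating a three-class cancer-stage cohort with Weibull event times
    and administrative censoring, and an experiment runner for Monte
    Carlo simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    ranger,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
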