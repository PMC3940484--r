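Package: protcal
Title: Calibration of Whole-Proteome Abundance Surveys and Variance
    Decomposition of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recalibrates label-free whole-proteome abundance surveys
    against gold-standard individual protein measurements using two-part
    (change-point) log-log regression with leave-one-out cross-validated
    model selection and a parametric bootstrap likelihood-ratio test.
    Decomposes the variance in protein expression between genes into the
    contributions of transcription, mRNA degradation, translation and
    protein degradation under two independent errors-in-variables
    strategies, compares measured (ribosome-profiling) and inferred
    translation-rate distributions, and performs a trimodal census of
    highly-expressed, low-expressed and non-expressed genes.  A
    synthetic-data generator reproduces the statistical structure the
    analysis assumes so that every stage can be tested against known
    ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
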