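Package: bht
Title: Brain Health Test Dementia Screening Instrument and Validation Toolkit
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Brain Health Test (BHT), a two-stage dementia
    screening instrument for primary care: a weighted risk score with
    high-risk triage, a 16-point brief cognitive test (BHT-cog), and the
    combined two-stage screening decision. Also provides the closed-form
    diagnostic-evaluation statistics used to validate such instruments
    (confusion-matrix metrics, odds ratios with Woolf confidence intervals,
    ROC/AUC with Hanley-McNeil intervals, Youden-optimal cutoffs), cohort
    CSV input/output with record validation, packaged summary fixtures of
    the development cohort, and a seedable synthetic three-group cohort
    simulator calibrated to the published group distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
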