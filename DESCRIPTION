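Package: chairstand
Title: Sit-to-Stand Transition Detection for the Instrumented 30-Second Chair-Stand Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts sit-to-stand transitions in 30-second chair-stand tests
    recorded as distance-versus-time signals from a chair-mounted ultrasound
    range sensor sampled at 10 Hz. Implements two detection algorithms: a
    moving-median filter with peak-distance and peak-height thresholds, and a
    moving-minimum filter with an adaptive sitting-standing threshold and a
    merge/discard cascade. Also provides grid-search calibration of detector
    parameters against manual counts, inter-rater reliability statistics
    (two-way absolute-agreement single-rater intraclass correlation with
    confidence intervals and reliability bands), normative classification of
    test scores by gender and age band, classifier evaluation against a
    no-information rate (exact binomial test, Clopper-Pearson intervals,
    arcsine effect size and power), and a seeded synthetic-signal generator
    that emulates young-subject and older-subject noise regimes with exact
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
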