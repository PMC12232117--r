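Package: photobout
Title: Event-Locked Fiber Photometry and Lick-Bout Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bout-locked neurotransmitter dynamics
    measured with two-channel (465/405 nm) fiber photometry during ingestive
    behavior. Detects lick bouts (clusters of three or more licks separated
    by at least 10 s), corrects the sensor channel with an FFT-based
    isosbestic subtraction, builds fixed-layout peri-bout snips z-scored to
    their own 5-s baselines, performs bootstrapped waveform inference with a
    consecutive-bin significance rule, epoch AUC quantification, and the
    accompanying group statistics (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Holm post hocs, planned paired
    comparisons, Welch ANOVA with Monte-Carlo Dunnett). A synthetic-data
    module generates lick sessions, photometry streams, multispout trial
    tables and in vitro ROI traces with known ground truth so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
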