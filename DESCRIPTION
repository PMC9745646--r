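Package: basewear
Title: Reliable Baseline Periods for Perioperative Wearable Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how long surgical patients must be
    telemonitored at home before reliable individual baseline values of
    heart rate, daily step count, and patient-reported outcomes are
    obtained. Implements a measurement/day/patient exclusion cascade for
    minute-level wearable data (technical-range filtering and detection of
    sensor-removal artifacts from joint temperature-drop and heart-rate
    anomaly signatures), per-patient reference values over the preoperative
    phase, reliability of randomly selected contiguous measurement periods
    via the intraclass correlation coefficient (two-way random effects,
    absolute agreement) with F-based confidence intervals, Bland-Altman
    limits of agreement, and perioperative-course summaries. A synthetic
    cohort generator with known variance structure makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
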