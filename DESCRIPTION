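Package: wearhr
Title: Repeatability and Sensitivity Analysis of Smartwatch Heart-Rate Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning wrist-worn photoplethysmography heart-rate
    streams and device-reported sleep-state events into digital biomarkers,
    and for evaluating those biomarkers in small parallel-group trials.
    Nightly sleep intervals are reconstructed from sleep-state change
    events, heart-rate samples are split into asleep and awake segments,
    and each subject-day segment is summarised by its 2.5th, 50th and
    97.5th percentiles. Random-intercept linear mixed models (REML, via
    nlme) provide intraclass correlation coefficients, minimum detectable
    effects, treatment-by-day contrasts against the averaged predose level
    with Bonferroni correction, and Cohen's d effect sizes. A synthetic
    smartwatch-data generator with known ground truth supports parameter
    recovery and operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    optparse
Config/testthat/edition: 3
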