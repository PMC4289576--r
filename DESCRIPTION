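Package: faindex
Title: Functional Ability Index for Frailty Screening in Community-Dwelling
    Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, classification and predictive-validity analysis for a
    self-report Functional Ability (FA) index that counts six frailty risks
    and six robustness resources from eleven questionnaire items and
    cross-classifies community-dwelling seniors into Robust, postRobust,
    preFrail and Frail. Provides a calibrated synthetic-cohort generator
    (latent-trait item model, class-dependent covariates, exponential
    event-time hazards over a 93-month horizon, wave-to-wave class
    transitions), censored time-to-event analysis (Kaplan-Meier and
    actuarial life tables, k-sample log-rank tests, proportional-hazards
    regression with likelihood-ratio tests), descriptive statistics
    (Spearman rank correlations, Fisher's exact tests, Welch t-tests,
    class-profile and transition tables), and a reproducible
    simulate-score-analyze-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
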