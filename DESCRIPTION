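Package: pvonset
Title: Disproportionality and Time-to-Onset Analysis of Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pharmacovigilance analysis of spontaneous-reporting-
    system (SRS) databases laid out in the four-table JADER schema (demo,
    drug, reac, hist). Implements reporting odds ratio (ROR) signal
    detection on 2x2 contingency tables with Woolf confidence intervals,
    Weibull time-to-onset modelling with shape-parameter hazard
    classification (initial / random / wear-out failure), Kaplan-Meier and
    log-rank comparison of onset profiles between two exposure groups, and
    outcome profiling with mosaic-plot geometry. Ships a calibrated
    synthetic report generator with closed-form expected contingency cells
    so that every analysis stage can be validated against a known
    generative truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
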