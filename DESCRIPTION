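Package: memdecline
Title: Sex- and Stage-Stratified Modelling of CSF Biomarker Change and Verbal Memory Decline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how within-person change in the cerebrospinal fluid
    pTau181/Abeta42 ratio relates to verbal memory decline in the preclinical and
    mild cognitive impairment (MCI) stages of Alzheimer's disease, and how that
    relationship is moderated by sex. Implements regression-based normative scoring
    of neuropsychological tests, actuarial (Jak/Bondi) diagnostic staging with
    biomarker-based preclinical-AD labelling, lagged-residual change scores for
    repeated measures, and random-intercept linear mixed models with up to
    three-way interactions, reported with Wald intervals, variance components and
    the intraclass correlation. A seeded synthetic-cohort generator with built-in
    effect-size presets supports estimator validation by Monte-Carlo parameter
    recovery, type-I-error calibration and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
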