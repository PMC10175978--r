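Package: bzdbp
Title: Doubly Robust Estimation of Sedative Prescribing Effects on Blood
    Pressure from Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating average treatment effects (ATE) of incident
    short- and long-term benzodiazepine / z-drug (BZD) management on systolic
    and diastolic blood pressure from longitudinal general-practice records.
    Provides prescription-episode construction under a new-user design,
    window-based blood-pressure outcome derivation, practice-level data-quality
    and patient-eligibility cohort filters, multiple imputation by chained
    equations with Rubin's-rule pooling, and augmented inverse-probability
    weighted (AIPW) doubly robust estimation for a three-level treatment with
    practice-clustered influence-function variance, plus crude and adjusted
    linear-regression comparators, age-stratified and drug half-life
    sensitivity analyses. A synthetic electronic-health-record generator with
    known ground truth supports parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    nnet,
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
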