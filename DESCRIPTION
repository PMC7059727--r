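Package: icustatsel
Title: Summary-Statistic Featurization and Genetic-Algorithm Statistic
    Selection for ICU Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for representing irregular ICU physiological time series
    by a catalogue of 14 distribution summary statistics (central tendency,
    dispersion and distribution shape), for cleaning MIMIC-style event
    tables (observation-window restriction, de-duplication, box-plot plus
    clinical-range outlier handling, patient/predictor/statistic missingness
    filters, mean imputation), and for searching combinations of statistics
    with a binary-encoded genetic algorithm embedded in repeated nested
    cross-validation.  Supports mortality (72-hour, in-hospital, 30-day,
    1-year), length-of-stay regression and multilabel diagnosis-group
    prediction with random-forest and logistic-regression backends, derives
    statistic-importance tables (selection frequency, mean outer-test
    metrics), and ships a synthetic electronic-health-record cohort
    generator with planted, recoverable statistic-level signal for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    arrow,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
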