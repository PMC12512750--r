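Package: icpsweep
Title: Microwave Frequency-Sweep Pipeline for Noninvasive Intracranial
    Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing, feature engineering, feature
    selection and regression for noninvasive intracranial-pressure (ICP)
    estimation from two-port microwave S-parameter sweeps. Includes a
    pressure-coupled phantom-measurement simulator, Touchstone (.s2p)
    input/output with reference-stream synchronization, optimal-band
    selection from temporal variation of the reflection magnitude,
    overlapping dataset variants with trial-disjoint splits, two-level
    spectral feature extraction (extrema, area under the curve, group
    delay distortion, percent amplitude of fluctuation, differential
    multistatic data matrices), correlation-ranked ordered feature
    selection, and a fixed catalogue of 25 regression presets evaluated
    by MAE, RMSE and R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
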