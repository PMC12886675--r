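Package: multisense
Title: Simulation and Multi-Task Deep Learning Analysis for Multiplexed
    Wearable Biosensor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing six-analyte interstitial-fluid biomarker
    panels measured by a multiplexed electrochemical microneedle patch
    (glucose, uric acid and cholesterol by chronoamperometry; sodium,
    potassium and pH by open-circuit potentiometry). Provides a synthetic
    cohort generator for chronic diet studies and acute interventions, a
    sensor digital twin (linear and Nernstian forward models with noise,
    drift, interference and motion artifacts), calibration fitting with
    analytical figures of merit (limit of detection, selectivity drift,
    signal retention, relative standard deviation), a from-scratch
    multi-task 1-D convolutional network that jointly classifies health
    condition and regresses a continuous health degree under stratified
    fivefold cross-validation, classical machine-learning baselines, and
    interpretability via exact Shapley attribution and t-SNE separability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    cluster,
    class,
    e1071,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
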