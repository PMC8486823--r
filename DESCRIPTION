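Package: wearpipe
Title: Wearable Sensor Streams to Daily Features and Phenotype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible desk-scale pipeline for longitudinal consumer
    wearable data: time-shift de-identification of event-timestamped heart
    rate, step and sleep-stage streams, minute-level harmonization (cleaning,
    sleep binarization, trailing rolling smoothing), twelve domain-knowledge
    daily features via heart-rate stratification, 84 user-level summary
    features, repeated 5-fold cross-validated elastic-net logistic
    classification of binary phenotypes with train-only power-transform
    normalization and pooled AUROC / average-precision evaluation, and a
    2-D embedding of the day-level feature space. A synthetic-cohort
    generator with circadian structure, sleep bouts, activity bouts,
    missingness and configurable label-linked effects makes every stage
    testable without access to real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    glmnet,
    ggplot2,
    jsonlite,
    generics,
    vegan,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
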