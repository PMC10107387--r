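Package: pretermlsdl
Title: Threshold-Decomposition Learning and Prediction for Preterm-Labour
    Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for predicting preterm versus term delivery
    from physiological signals recorded during active labour: synthetic
    two-class cohorts of uterine-contraction (EHG) envelopes and maternal or
    foetal beat-to-beat RR series; epoch averaging and disjoint windowing;
    the Linear Series Decomposition Learner (LSDL), an amplitude-threshold
    signal decomposition fitted by maximising a normalised-Euclidean
    class-separability cost; a 20-dimensional time/frequency/nonlinear
    feature ensemble; SMOTE class balancing; eight supervised classifiers
    under stratified 10-fold cross-validation; and two-cluster K-Means and
    Gaussian-mixture partitioning with per-class accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pROC,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
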