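Package: motorei
Title: Quantitative Upper-Limb Motor-Function Evaluation from Wearable
    Inertial and Surface EMG Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes quantitative evaluation indicators (EIs) of hemiparetic
    upper-limb motor function from fused wearable sensor recordings: ten
    surface electromyography channels at 1000 Hz and two six-axis inertial
    measurement units at 100 Hz.  Task repetitions are segmented from
    gyroscope activity, seven feature families are extracted per repetition,
    each subject is scored against a healthy reference bank (Pearson
    correlation, dynamic time warping, Euclidean power-distribution
    distances), and one-dimensional indicators are learned by PCA,
    Sammon-criterion multidimensional scaling, non-negative matrix
    factorization, or L1-penalized regression.  Validation follows a
    leave-one-subject-out protocol with normal-range, variation-rate and
    determination-coefficient summaries.  A synthetic-cohort
    generator emulates healthy and impaired subjects (slowing, weakness,
    tremor, co-contraction) so the full pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    MASS,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
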