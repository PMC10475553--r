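Package: foiselect
Title: Hybrid Feature Selection for Fluorescence Optical Imaging Readings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step hybrid feature selection and differential-diagnosis
    modelling for binary fluorescence-optical-imaging (FOI) feature readings
    of the hands. Provides a synthetic reading-cohort generator with planted
    univariate effects and XOR-style interactions, preprocessing (hand
    fusion, binary feature-phase encoding, zero-feature and featureless
    patient filtering, One-vs-One/One-vs-Rest problem construction,
    stratified holdout splitting, minority oversampling), association
    metrics (phi coefficient with significance testing, pairwise phi and
    variance-inflation collinearity screening, the MultiSURF relief
    algorithm), a cross-validated gradient-boosted tree engine with
    grid-search tuning, mean-decrease-impurity and permutation importance,
    and multi-list sequential forward selection with transition-point
    determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
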