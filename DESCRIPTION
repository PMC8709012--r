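Package: fundusNCAR
Title: Residual CNN+LSTM Deep Features and Multilevel NCA/ReliefF Feature
    Selection for Fundus-Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ophthalmic-image classification experiments: a
    residual CNN+LSTM hybrid network (implemented as a small seeded,
    CPU-only neural-network engine) used as a deep-feature extractor from
    fundus images; the NCAR multilevel feature-selection algorithm, which
    combines neighbourhood component analysis (NCA) feature weighting with
    ReliefF importance weighting under successive thresholds; and a
    stratified cross-validation harness reporting per-class sensitivity,
    specificity, precision, F-score and one-vs-rest AUC for DT, LD, NB,
    SVM and KNN classifiers.  Synthetic feature tables and eight-class
    fundus-like phantom images with known ground truth make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    withr,
    e1071,
    rpart,
    MASS,
    pROC
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
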