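Package: sonotex
Title: Texture Radiomics and SVM Classification for Ultrasound Breast Lesion Characterisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for grey-level texture analysis of masked
    regions of interest in 2D ultrasound images and downstream machine-learning
    classification of breast tissue. Implements masked-ROI grey-level
    normalization to the mean plus/minus three standard deviations, a
    47-feature texture engine (histogram, grey-level co-occurrence, run-length
    and size-zone matrix features), patient-disjoint balanced data splitting,
    radial-basis support vector machine classification with grid search and
    recursive feature elimination with cross-validation, and an evaluation
    layer with ROC/AUC confidence intervals, DeLong comparison of correlated
    ROC curves, intraclass correlation and per-feature group statistics.
    Ships a synthetic speckle-phantom cohort generator so the whole pipeline
    is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
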