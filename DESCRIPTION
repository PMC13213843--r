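Package: anfisdd
Title: Explainable Neuro-Fuzzy Screening for Early Developmental Disability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, training and evaluation toolkit for an Adaptive
    Neuro-Fuzzy Inference System (ANFIS) screening classifier for early
    developmental disability in children aged 1 to 6 years. Provides a seeded
    synthetic cohort generator with group-conditional truncated-normal
    assessment scores, deterministic preprocessing (sex encoding, missing-data
    policy, min-max scaling, stratified splitting), engineered cross-domain
    and composite-risk features, a five-layer Sugeno ANFIS with Gaussian
    membership functions trained end-to-end by Adam gradient descent,
    confusion-matrix and ROC evaluation with stratified cross-validation and
    perturbation-based feature importance, and interpretable clinical reports
    with confidence stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
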