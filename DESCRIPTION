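Package: smfdx
Title: Serum Metabolic Fingerprint Diagnostics with Locally Connected Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case/control diagnostic modelling of serum metabolic
    fingerprints (SMFs) acquired by laser desorption/ionization mass
    spectrometry. Provides peak-list binning onto a fixed m/z grid,
    total-ion-current normalization and cosine reproducibility checks; a
    locally connected one-dimensional neural classifier (unshared filter
    weights) with an optional multi-modal variant that fuses clinical
    indexes into the fully connected stage; classical baselines including a
    from-scratch OPLS-DA; a full ROC evaluation harness (DeLong confidence
    intervals and paired tests, Youden thresholds, stratified
    cross-validation, label-permutation tests, power analysis); gradient
    saliency maps for metabolite feature-panel selection; and a synthetic
    cohort generator with planted discriminative structure so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mzR,
    withr,
    optparse
Config/testthat/edition: 3
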