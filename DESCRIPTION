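Package: pdgwo
Title: Grey Wolf Optimization and Image-Pipeline Tools for Parkinson's
    Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building grey-wolf-optimized deep-learning
    classifiers of Parkinson's disease from axial brain images. Provides a
    from-scratch grey wolf optimization (GWO) engine for bounded continuous
    minimization, a mixed integer/continuous hyperparameter search layer
    driven by it, a framework-independent declarative builder with exact
    feature-map shape inference for five architectures (including a hybrid
    VGG16 plus inception-reduction design), a DICOM preprocessing and
    dataset-splitting pipeline (empty-slice filtering, skull stripping,
    crop/resize), binary-classifier evaluation metrics with ROC/AUC, and a
    deterministic synthetic phantom generator so the whole pipeline is
    testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    withr
Config/testthat/edition: 3
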