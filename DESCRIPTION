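Package: molimage
Title: Compound Potency Prediction from 2D Structure Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based QSAR workbench: curates ChEMBL-style IC50
    activity tables into per-compound pIC50 records, renders standardized
    molecules as fixed-size Kekule structure images, and predicts potency
    on a continuous scale with convolutional network regressors built on
    classic image backbones (AlexNet, VGG-19-bn, ResNet-152,
    DenseNet-201) carrying single- or multi-task regression heads.
    Includes fully-connected network and Random Forest baselines on
    circular (Morgan-type) fingerprints, cyclic step-decay learning-rate
    schedules with early stopping, grid search, prediction ensembles,
    Y-scrambling, residual diagnostics, and a treatment-coded factorial
    linear-model comparison of runs. A synthetic structure-activity
    generator with known ground truth makes the whole pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    car,
    graphics,
    grDevices,
    jsonlite,
    methods,
    png,
    randomForest,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
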