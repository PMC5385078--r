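Package: idcscore
Title: Image-Based Severity Scoring of Soybean Iron Deficiency Chlorosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for rating soybean iron deficiency
    chlorosis (IDC) severity from RGB canopy images on the standard 1-5
    field visual rating scale. Includes color-chart white balance and
    hue-drift calibration, HSV saturation/hue canopy segmentation with
    largest-connected-component cleanup, extraction of the yellow and
    brown canopy-area percentage features (Y%, B%), flat and two-step
    hierarchical severity classifiers, cost-sensitive confusion-matrix
    evaluation with repeated k-fold cross-validation, population canopy
    graph (decision boundary) construction, and a synthetic canopy
    generator with planted ground truth for testing every stage without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    MASS,
    e1071,
    rpart,
    randomForest,
    mclust,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
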