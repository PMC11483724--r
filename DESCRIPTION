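Package: thromboCNN
Title: Convolutional Neural Network Prediction of Stroke Thrombus Red
    Blood Cell Content from Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the histological red blood cell (RBC)
    content of retrieved ischemic-stroke thrombi from 3-channel
    multiparametric MR image slices (R2* map, quantitative susceptibility
    map, late-echo gradient-echo magnitude). Provides a calibrated
    synthetic thrombus cohort generator with ground-truth RBC content, a
    preprocessing stage (pooled z-score normalization, fixed 49 x 56
    canvas), a three-component training-set augmentation scheme (input
    sampling equalization, dataset duplication, random geometric
    transformation), a small 3-convolutional-layer CNN regression engine
    trained with Adam on the half mean squared error, and a grouped 8-fold
    cross-validation driver with slice-to-thrombus median aggregation and
    a full regression/classification metric suite (accuracy within a
    tolerance, mean absolute error, Pearson r, regression slope,
    sensitivity, specificity, rank-based AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
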