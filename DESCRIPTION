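Package: hsisoa
Title: Hyperspectral Discrimination of Herbicide Site of Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for discriminating herbicide site of action
    (SOA) from line-scan hyperspectral images of treated plants: flat-field
    reflectance calibration against dark/white reference frames, red-edge
    convolution segmentation of plant pixels, mean-spectrum extraction with
    band cropping and Savitzky-Golay smoothing, chemometric preprocessing
    (log(1/R), multiplicative scatter correction, mean centering) with strict
    train-fit/test-apply semantics, exploratory NDVI t-test heatmaps and
    random-forest band importance, and one-vs-one PLS-DA / SVM ensembles with
    soft voting, leave-one-out cross-validation and day-to-day validation.
    Includes a synthetic scene and study generator with known ground truth so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    graphics,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
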