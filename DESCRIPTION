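Package: pupilgrid
Title: Pupil-Center Localization by Coordinate-Marginal Softmax Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the pupil center in infrared eye images by casting 2-D
    localization as classification over pixel positions. Provides a
    low-resolution fully-connected classifier (one class per pixel of a
    20x15 image) and a high-resolution pair of slim convolutional networks
    that independently predict the x- and y-coordinates of the pupil center
    in 320x240 images, reducing the output layer from h*v to h+v neurons.
    Includes a seeded synthetic infrared-style eye-image renderer with
    controllable difficulty (elliptical pupils, corneal glints, eyelash
    occluders, eyelids, illumination gradients, sensor noise), mini-batch
    SGD training with cross-entropy loss and L2 weight decay under a staged
    learning-rate schedule, and evaluation via per-image Euclidean pixel
    error, detection rate at k pixels (DRk), and error dispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
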