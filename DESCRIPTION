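Package: flatnet
Title: Heat-Map Landmark Localization for Midsagittal Vocal-Tract Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the 21 anatomical landmarks of the vocal-tract area on
    midsagittal grayscale images with the Flat-net approach: landmark
    coordinates are encoded as per-landmark Gaussian heat-map channels
    (sigma = 10 px, peak 1), generated by a pooling-free fully-convolutional
    network built from a five-way dilated 9x9 convolution bank, and decoded
    back to pixel coordinates by per-channel argmax. Includes the
    keypoint-consistent ten-transform data-augmentation pipeline, a seeded
    synthetic phantom corpus generator with exact ground truth, and an
    evaluation harness implementing per-landmark Euclidean distances, RMSE,
    5-pixel outlier rates, paired t-tests, randomized 10-fold
    cross-validation and leave-one-subject-out protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, png, jsonlite, stats, utils, graphics, tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), tiff, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
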