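Package: carehar
Title: Nurse-Care Activity and User Recognition from Tri-Axial Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising complex nurse-care activities and identifying
    the performing nurse from a single body-worn tri-axial accelerometer.
    Implements label-preserving time-series augmentation (jitter, scaling,
    magnitude warping, time warping, rotation) with class balancing, two-step
    feature extraction (a 13-channel intermediate feature set including
    orientation angles, and 117 statistical features per segment including the
    MSUM extremum-gap statistic), Pearson-correlation pruning with random-forest
    impurity ranking and saturation-curve feature selection, a multi-branch
    stacked 1-D convolutional network, a CART random forest, weighted
    probability fusion of the two, and a leave-one-subject-out evaluation
    harness. A seeded synthetic accelerometer generator with controllable class
    imbalance, noise and missingness makes the whole pipeline testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
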