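Package: selfcalrf
Title: Self-Calibrating Random Forests for Myoelectric Gesture Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed surface-EMG feature extraction and a random-forest
    gesture decoder that adapts to a new user from a single calibration
    trial per gesture (reduced-error tree pruning plus appended
    user-specific trees) and then keeps itself calibrated during use
    without labels, by buffering test windows, pseudo-labeling them with
    t-SNE manifold embedding and prediction-seeded K-Means, and retraining
    a fraction of the appended trees after each testing block. Includes a
    seeded synthetic EMG generator that emulates arm-position distribution
    shift and a replay harness for the 11-block arm-rotation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
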