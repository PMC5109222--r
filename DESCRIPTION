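Package: instantemg
Title: Gesture Recognition from Instantaneous High-Density Surface EMG Images
Version: 0.1.0
Authors@R:
    person("EMG", "Imaging Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps each sampling instant of a high-density surface
    electromyography (HD-sEMG) electrode grid to a grayscale image and
    recognises hand gestures frame by frame. Provides the instantaneous
    sEMG image transform and difference images, signal conditioning
    (Butterworth power-line band-stop, rectification, envelope low-pass,
    MVC normalisation, spatial median filtering, decimation, circular
    shift augmentation), a small eight-layer convolutional network with
    locally connected layers, batch normalisation recalibration and the
    full SGD training recipe, five classical baselines on raw
    instantaneous vectors, majority voting over frame decisions with
    voting-window curves and standard cross-validation protocols, a
    synthetic HD-sEMG generator (amplitude-modulated band-limited noise
    and motor-unit action-potential trains), dataset importers (MAT v5,
    HDF5) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    FNN,
    MASS,
    png,
    rhdf5,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
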