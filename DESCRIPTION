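Package: skiseg
Title: Unsupervised Segmentation of Alpine Skiing Activity from Smartphone IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a continuous six-axis smartphone inertial recording of a
    skiing day into Skiing and Not-Skiing intervals without labelled training
    data. Tracks sensor orientation with a quaternion complementary filter to
    isolate gravity on the world-frame Y axis, smooths the world-frame signals
    with a two-stage moving-average plus Butterworth filter, extracts windowed
    time- and autocorrelation-domain features, normalises them to [-1, 1] with
    optional principal-component reduction, and clusters windows into two
    activity classes with k-means, Gaussian mixtures, or Ward linkage. Includes
    a synthetic session generator with known ground truth, per-sample accuracy,
    Rand/adjusted-Rand and normalised-mutual-information evaluation, and a
    window-size by sliding-rate model-selection grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    signal,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
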