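Package: fieldfatigue
Title: Fatigue Prediction from a Single Chest Sensor with a 1-D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating physical and cognitive fatigue during
    long-duration field exercise from a single chest-worn sensor
    (tri-axial accelerometry at 100 Hz and single-lead ECG at 250 Hz)
    plus a 1 Hz GPS track.  Provides a synthetic protocol-session
    generator with ground-truth fatigue, terrain and activity; cadence
    based activity labelling from vertical-axis zero crossings; waypoint
    and slope assignment from the GPS track; continuous fatigue labels
    built from hourly performance tests (long-term linear fit and
    inter-test interpolation); non-overlapping window segmentation into
    a (D, W, F) tensor; a multi-channel 1-D convolutional regression
    network trained with Adam on mean absolute error; and rolling-window
    MAE/RAE evaluation per activity type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
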