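Package: whiskertask
Title: Analysis of Whisker-Based Aperture Discrimination in Freely Moving Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for go/no-go whisker
    aperture-discrimination experiments in freely moving mice: trial scoring
    and signal-detection performance (d-prime, running learning curves,
    moment of insight, lick-latency fits), whisker and locomotion kinematics
    (band-pass filtering, Hilbert whisking phase, behavioral-state
    segmentation, occupancy maps), per-unit tuning statistics with
    circular-shift shuffle nulls (touch modulation, onset latency, whisking
    angle and phase tuning, head angle, spatial tuning with a speed nuisance
    term), and cross-validated decoding of aperture width from spike counts,
    whisker angles, and calcium transients. A synthetic-session generator
    with known ground truth makes every stage testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    stats,
    signal,
    minpack.lm,
    e1071,
    glmnet,
    splines,
    pROC,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
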