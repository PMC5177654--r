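Package: ukfbmi
Title: Unscented Kalman Filter Decoders for Brain-Machine Interface Cursor Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding 2D cursor kinematics from binned motor
    cortical spike counts. Implements a family of Kalman-filter decoders:
    the position-velocity Kalman filter, a FIT-style variant with
    position-as-feedback and intention estimation, and two n-th order
    unscented Kalman filter decoders whose observation models add
    kinematic magnitudes, acceleration, position-velocity interaction,
    target position and distance, and population spiking history. Includes
    ridge fitting of encoding models, physics-based and fitted state
    transition models, closed-loop refinements (position-velocity output
    mixing, a chi-squared movement threshold, future-tap read-out), a
    synthetic center-out/pursuit session simulator with a generative
    neural population and a feedback user model, and evaluation harnesses
    for offline reconstruction, encoding prediction, and Fitts's-law
    closed-loop metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
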