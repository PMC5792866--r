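Package: moveresponse
Title: Detecting Movement Responses of Tagged Cetaceans to Capture and
    Noise Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and time behavioural responses of biologged
    marine mammals to discrete disturbance events such as capture/tagging
    and short underwater noise exposures. Extracts horizontal movement
    parameters (step length, speed, absolute turning angle) from GPS
    tracks and vertical parameters (dive duration, maximum depth, bottom
    wiggliness, post-dive surface duration) from 1 Hz time-depth records,
    removes diel and individual variation with a cyclic hour-of-day
    smoother under AR(1) errors, and fits piecewise linear (broken-line)
    regressions to hourly mean residuals with AICc model ranking, slope
    validation and bootstrap confidence intervals for breakpoint times.
    Includes a synthetic biologging data generator with known injected
    responses and a log-range transmission-loss model for estimating
    received airgun noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
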