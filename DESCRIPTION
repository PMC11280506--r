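Package: legacc
Title: Activity-Intensity Cut-Points from Ankle Accelerometry in Pre-Ambulatory Infants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies physical-activity intensity of pre-ambulatory infants
    from ankle-worn tri-axial accelerometers. Converts raw 20 Hz signals into
    gravity-free, leg-length-adjusted acceleration, derives epoch-level areas
    under the acceleration-time and jerk-time curves on 2-s non-overlapping
    windows, calibrates sedentary/light/moderate-to-vigorous cut-points
    against video-coded gold-standard intervals by true-positive-rate and
    predicted-activity-proportion optimization, and evaluates classifications
    with confusion-matrix metrics (TP/TN rate, PAP, MTPR, PMR). Includes a
    seeded synthetic-session generator for fixtures and parameter-recovery
    experiments, and published cut-points packaged as defaults.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
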