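Package: heartsnap
Title: Smartphone-Based Heart Rate and VO2max Measurement Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and validation toolkit for smartphone-based
    cardiorespiratory fitness measurement. Estimates heart rate from
    fingertip camera photoplethysmography channel means by windowed
    autocorrelation with per-channel confidence scoring and red/green
    fusion; estimates VO2max from 3-minute step-test heart-rate recovery
    (Tecumseh/Milligan) and 12-minute run-test distance (Cooper); computes
    run distance from privacy-preserving 1 Hz relative-displacement GPS
    records, raw and Savitzky-Golay smoothed; classifies skin tone by the
    CIELAB individual typology angle; and provides the agreement statistics
    used to validate such measurements (Lin concordance, Bland-Altman,
    intraclass correlation, percent error, confidence-cutoff retention).
    Includes seeded synthetic-data generators so every stage is testable
    offline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    geosphere,
    withr
Config/testthat/edition: 3
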