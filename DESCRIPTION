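Package: patd
Title: Physical Activity Type Detection from Wearable Accelerometer and GPS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying physical activity types (lying,
    sitting, standing, walking, non-level walking, running) from body-worn
    tri-axial accelerometers (nominal 50 Hz, five placements: chest, hips,
    pocket, knee) and GPS (nominal 1 Hz). Provides windowed time- and
    frequency-domain feature extraction, GPS speed and elevation features,
    random-forest models per sensor position or fused across positions,
    leave-one-subject-out evaluation designs for within- and between-age-group
    transferability, and a synthetic two-cohort data generator for testing
    every pipeline stage without access to field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
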