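Package: romkin
Title: Automated Joint Range-of-Motion Measurement from 2D Pose Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markerless video goniometry for the upper extremity. Computes
    per-frame joint angles from 2D pose landmarks via the planar atan2
    formula, extracts maximum range of motion (ROM) as the largest angle
    over all frames, and provides the full method-agreement toolkit used to
    validate such tools against manual goniometry: mean difference, Pearson
    correlation, two-way random-effects intraclass correlation, per-subject
    coefficient of variation, regression R-squared, paired t tests, and
    normal-approximation power/sample-size calculation. Ships a
    ground-truthed synthetic planar arm-motion generator, a deterministic
    color-marker pose backend for download-free end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
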