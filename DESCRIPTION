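Package: growthgate
Title: Age-Specific Reference Bands for Error Gating of Remote Anthropometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds smoothed age-specific quantile reference curves for adult
    anthropometric measurements (height, weight, BMI, waist, hip) from noisy
    remote-healthcare records, segments the age axis into growth-pattern groups
    with an exhaustive two-breakpoint piecewise-linear fit, and uses the curves
    to predict a per-patient acceptance band that flags suspicious values at the
    point of data entry. Includes a calibrated synthetic-cohort generator with
    labelled data-entry corruptions (unit conversion, digit transposition,
    offset and keystroke errors) for end-to-end validation, and a command-line
    pipeline covering simulation, preprocessing, reference building,
    segmentation, gating and reference updates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
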