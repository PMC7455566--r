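Package: fdimap
Title: Feature Diagnosticity Mapping for Natural Image Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reverse-correlation tools for measuring the relative importance
    of low-level visual features in image recognition. Images are reduced to
    a sparse bank of Gabor wavelets via an iterative coarse-to-fine
    decomposition; recognition is probed with random feature subsets, and
    each feature's diagnostic value (FDi) is estimated from response
    accuracy, z-scored within participant and image. Includes split-half
    replicability with a permutation null, spatial-frequency/eye-distance/
    center-distance bin ANOVAs with group contrasts, per-trait
    reliance-on-detail statistics with robust regression against clinical
    trait diagnosticity, and a simulated-observer cohort generator so the
    whole pipeline can be exercised and calibrated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    car,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
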