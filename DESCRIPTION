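Package: binoica
Title: Eccentricity-Resolved Independent Component Analysis of Binocular Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the statistics of binocular natural
    images vary with visual-field position. Provides a synthetic verged
    stereo-pair generator with ground-truth horizontal and vertical
    disparity fields, eccentricity- and quadrant-resolved patch sampling,
    patch normalisation and truncated PCA whitening, fixed-point
    Independent Component Analysis, per-eye Gabor fitting of the learned
    binocular filters, and the derived disparity statistics (position,
    phase and orientation disparity, binocular energy ratio) with
    bootstrapped distribution summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
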