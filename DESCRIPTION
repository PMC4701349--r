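Package: lfareader
Title: Automated Reading of Lateral Flow Test Card Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads photographed lateral flow immunoassay test cards:
    registers the card against a stored template with ORB binary features
    and a RANSAC homography, segments the colored strip labels with
    per-channel Otsu thresholding and contour filters, extracts and
    normalizes one-dimensional lateral intensity histograms, and
    classifies control, test-line and alcohol-pad signals with small
    hyperbolic-tangent multilayer perceptrons that include a reject
    option. Ships seeded synthetic generators for test-card images and
    labeled histogram datasets so every stage can be exercised and
    validated without physical devices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
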