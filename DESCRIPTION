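Package: octospot
Title: Octagon-Division Spot Detection for Brain MRI Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects bright compact tumor-like spots in 2-D grayscale brain
    images. Implements a hybrid segmentation stage (morphological or central
    gradient, depth-lambda suppression of regional minima by morphological
    reconstruction, steepest-descent watershed, brightness z-score candidate
    selection), an iterative octagon-sector narrowing procedure that localizes
    the spot, a rationalization scoring step that confirms or rejects it, and
    an evaluation battery (MSE, PSNR, SSIM, Dice, confusion metrics, tumor
    area ratio and area error). A seeded phantom generator provides synthetic
    brain images with ground-truth masks so the full pipeline can be exercised
    and validated without clinical data. Reads single-frame grayscale DICOM
    and PNG images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
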