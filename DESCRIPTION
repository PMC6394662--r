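Package: colonysizer
Title: Colony Counting and Colony-Size Distribution Analysis for
    Clonogenic Survival Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Counts stained cell colonies on scanned culture-dish images
    and quantifies the colony-size distribution. The counting pipeline
    selects the highest-contrast RGB channel, applies Gaussian blurring
    and rolling-ball background subtraction, thresholds to a binary mask,
    restricts analysis to a circular region of interest inset from the
    dish rim, splits merged colonies by watershed segmentation of the
    distance transform, and filters detections by area and circularity
    (4*pi*area/perimeter^2). Colony sizes are exported to plain-text
    files, binned into histograms, and fitted with Weibull and Gaussian
    models by Levenberg-Marquardt nonlinear least squares, reporting the
    derived mean and spread of the size distribution. A synthetic plate
    generator with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    png,
    tiff,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    jpeg,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
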