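Package: pumpkinpheno
Title: Image-Based Measurement of Pumpkin Biophysical Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for measuring biophysical properties
    of pumpkin fruits and vines from RGB photographs with instance masks.
    Provides color-checker based color correction (least-squares estimation
    of a 3x3 or affine correction matrix), ruler-based pixel-to-millimetre
    calibration (grayscale, Gaussian blur, Canny edges, Hough line
    transform), morphometry of masked components (moment-based ellipse
    fitting, affine axis alignment for width, medial-axis skeletonization
    for length, HSV-range peel-color classification), evaluation metrics
    (MAE, MAPE, mask average precision), and a seeded synthetic-scene
    generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    EBImage,
    png,
    igraph,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
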