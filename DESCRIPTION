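Package: canopyfeat
Title: Color and Texture Feature Extraction from Canopy RGB Imagery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature-extraction pipeline for top-down RGB images of plant
    canopies. Implements percentile-based contrast stretching, plant/soil
    segmentation from multiple vegetation indices (ExG, MExG, CIVE) with
    Otsu thresholding and small-object cleaning, a bank of 35 image
    transforms (RGB channels, CIE XYZ and L*a*b*, HSI, Y'CbCr, and 20
    RGB-band vegetation indices), four population moment color features and
    nine gray-level co-occurrence matrix (GLCM) texture features per
    transform (455 features per image), location/time covariates, batch
    extraction to a rectangular feature table, prediction-evaluation
    statistics (RMSE, R-squared, Bias, Accuracy, Cohen's kappa), and a
    synthetic canopy-scene generator with ground-truth masks for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
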