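Package: tileseg
Title: Quantifying the Effects of Image Tiling on Semantic Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how sliding-window and corner-plus-center tiling
    of large images affects convolutional segmentation models at inference
    time. Provides tile-layout generation over 2D images and 3D volumes,
    stitching of per-tile probability maps under two aggregation rules
    (rounding after or before averaging), pixelwise Dice and instance-level
    polygon F1 scoring, a deterministic seeded U-Net-style forward engine
    built from first principles that exposes the translational variance of
    max pooling, flip and small-translation variance analysis for arbitrary
    segmentation functions, and generators for multi-channel MRI-like
    phantoms and synthetic building scenes with vector ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
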