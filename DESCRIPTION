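Package: pcead
Title: Progressive Context-Encoder Anomaly Detection for Tumor
    Segmentation in Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised tumor segmentation for H&E whole-slide images by
    anomaly detection. A progressive growing GAN is trained with a
    context-encoder inpainting objective on normal-tissue patches only;
    per-pixel absolute reconstruction errors are summarised by a
    multivariate Gaussian reference distribution, pixels are scored by
    Mahalanobis distance and thresholded at a quantile calibrated on
    held-out normal slides, and flagged pixels are polygonised into
    slide-coordinate tumor predictions. Includes Otsu tissue masking and
    patch tiling, a sharded binary record store for multi-resolution
    training patches, QuPath-compatible GeoJSON polygon IO, pixel-level
    polygon-based evaluation (sensitivity, specificity, F1, slide-level
    presence calls), and a seeded pseudo-histology slide simulator so the
    whole pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
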