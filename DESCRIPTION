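Package: organtraits
Title: Per-Organ Trait Extraction and Segmentation Evaluation for Plant Phenotyping Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement core for instance-based plant phenotyping of Arabidopsis
    rosette leaves and siliques (seed pods). Given an RGB image and an instance
    label map (from any segmenter, or from bundled classical baselines), computes
    a fixed catalog of 64 per-image traits per organ class: 35 morphological
    traits (perimeter, area, roundness, orthogonal and minimum-area bounding
    rectangles, convex hull), 7 chromatic-coordinate color traits, and 22 texture
    traits (7 Hu moment invariants and 15 gray-gradient co-occurrence matrix
    features). Includes the standard instance-segmentation evaluation suite
    (IoU-based matching, precision/recall/F1, difference in count, MAPE, R2
    agreement), classical segmentation baselines (excess-green + Otsu, K-means),
    LabelMe polygon rasterization, and a seeded synthetic rosette/silique scene
    generator with exact ground truth. All lengths and areas are in pixel units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    tibble,
    dplyr,
    readr,
    igraph,
    withr,
    ggplot2,
    generics,
    rlang,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
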