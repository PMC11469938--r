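Package: fibrotile
Title: Tile-Based Automated Ashcroft Grading and Morphometry of Lung
    Fibrosis Histology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@fibrotile.org",
           role = c("aut", "cre"))
Description: Automated histopathological grading of pulmonary fibrosis on
    whole-section lung histology rasters. Sections are downscaled, split
    into 512x512 tiles, and each tile is assigned an ordinal Ashcroft
    grade (0-8) or a non-alveolar class by a small convolutional
    classifier trained on labelled tiles; per-tile grades are aggregated
    into a tile-count-weighted whole-section composite score, rendered as
    grade heatmaps, and validated against manual grading with confusion
    matrices and Cohen's kappa. The package also provides positive-pixel
    area-fraction morphometry for collagen stains, whole-lobule
    stereology (Archimedes lobule volume, serial-section marker volume),
    and a procedural generator of labelled synthetic histology tiles and
    sections with known grade maps so the full pipeline is testable
    without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
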