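Package: slidetiler
Title: Tile-Based Batch Processing of Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterates a user-supplied per-tile analysis over gigapixel
    whole-slide images stored as pyramidal tiled TIFF, with configurable
    resolution series, tile size and overlap. Tiles are extracted with
    memory bounded by the tile, persisted under a coordinate-encoding
    file-name template, and handed to a processor function together with
    their slide context and a persistent results store, so independent
    per-tile steps can accumulate whole-slide measurements. Ships
    reference analyses for hematoxylin/DAB immunohistochemistry
    (color-deconvolution positivity per tile and per slide, retrieval of
    the maximum-positivity tile), a synthetic slide generator with exact
    stain-area ground truth for validation, and a command-line interface
    for unsupervised batch runs over slide folders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
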