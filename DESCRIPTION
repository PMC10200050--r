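Package: eggquant
Title: Automated Whitefly Egg Quantification and Plant Resistance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based quantification of whitefly eggs on microscope leaf
    images: surplus cropping and padded tiling of large images, a pluggable
    per-tile detector contract with a reference blob detector, overlap-merge
    duplicate suppression via exact intersection-over-union, size and
    confidence filtering, object-level and image-level evaluation metrics
    (precision, recall, F1, miss rate, counting accuracy, r-squared) with a
    confidence-threshold sweep, no-choice bioassay statistics (adult
    survival, oviposition rate, arcsine and square-root transforms, t-tests)
    for resistance screening, and a seeded synthetic leaf-scene generator
    with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
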