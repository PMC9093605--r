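Package: sproutquant
Title: Automated Quantification of Angiogenic Sprouting from Endothelial
    Spheroid Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Batch quantification of sprouting angiogenesis from
    single-channel fluorescence images of endothelial cell spheroids.
    Segments the total spheroid and its center by adaptive histogram
    equalization, Sobel edge detection, Gaussian edge-density spreading
    and adaptive thresholding; extracts a pruned sprout skeleton;
    classifies each sprout as attached to or migrated from the spheroid
    body; and reports per-spheroid morphometrics (areas, sprout counts,
    cumulative sprout length) to CSV. Includes a seeded synthetic-image
    generator with exact ground truth for end-to-end validation, and a
    non-interactive command-line interface for cropping, analysis and
    fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
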