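Package: nichespat
Title: Spatial Point-Pattern Statistics for Tissue Niche Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies clustering tendency and cell-cell proximity in
    two-dimensional tissue sections. Implements a subsampled Hopkins
    clustering-tendency protocol with a complete-spatial-randomness (CSR)
    Monte-Carlo envelope, a nearest-neighbor proximity test of a target cell
    population against a reference population using density-matched random
    null points, centroid extraction from binary label images, and a
    synthetic tissue-scene generator (follicle exclusion regions,
    perifollicular clustering, attraction between populations) for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
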