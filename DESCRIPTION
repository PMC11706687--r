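Package: rootzones
Title: Deterministic Segmentation and Ratiometric pH Analysis of Plant Root Developmental Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of dual-excitation (HPTS 458/405) fluorescence microscopy images of
    Arabidopsis thaliana root tips. Provides a residual U-block encoder-decoder
    (U-Net squared) semantic segmentation model for root developmental zones
    (background, root tissue, early/late elongation zone, meristematic zone) with
    fully deterministic, seed-controlled training; Monte Carlo Dropout epistemic
    uncertainty maps; Guided Grad-CAM attribution maps; pixel-wise 458/405
    ratiometric quantification with per-zone statistics and Welch's t-test group
    comparisons; OME-TIFF input/output; a synthetic root-tip image generator for
    testing; and an end-to-end analysis pipeline producing result images, CSV
    tables and an HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
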