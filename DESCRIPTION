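Package: soupclean
Title: Ambient RNA Contamination Removal for Droplet-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and removes cell-free ("ambient" or "soup") mRNA
    contamination from droplet-based single-cell RNA sequencing count
    matrices. Estimates the ambient expression profile from empty droplets,
    infers the contamination fraction either from user-supplied negative
    marker gene sets (with a Poisson test to exclude endogenously expressing
    cells) or by a fully automated marker-based procedure, and removes the
    expected soup contribution from each cell by capped proportional
    (multinomial maximum-likelihood) subtraction, optionally aggregated at
    the cluster level. Reads and writes 10x-style MatrixMarket count
    directories and includes a synthetic droplet-channel simulator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
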