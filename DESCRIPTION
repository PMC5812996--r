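Package: axonmps
Title: Quantification of the Axonal Membrane-Associated Periodic Skeleton in
    Super-Resolution Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects axons in single-channel super-resolution (STED)
    microscopy images, scores 1 um x 1 um axon-containing sub-regions by
    their maximal Pearson correlation against a modeled periodic lattice of
    Gaussian peaks spaced ~190 nm apart (the actin/spectrin membrane-associated
    periodic skeleton, MPS), and summarises a field by MPS abundance (fraction
    of sub-regions above a correlation threshold) and MPS correlation (mean
    correlation of the sub-regions above it). Also provides sub-pixel period
    estimation from line profiles by quadratic peak refinement, quantification
    of axonal fragmentation from binarized images, and a synthetic STED image
    simulator with full ground truth for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
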