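Package: molbit
Title: Design, Simulation and Decoding of Nanopore Molecular Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for molecular tagging with nanopore-readable DNA barcodes
    ("molbits"). Simulates raw nanopore current signals ("squiggles") from DNA
    sequences via a k-mer pore model, evolves sets of barcode sequences that are
    maximally mutually separable under dynamic time warping subject to synthesis
    constraints, trains a small 1-D convolutional network to classify raw signals
    to barcode identities, and encodes/decodes 32-bit messages into 96-bit
    presence/absence tags with a random linear error-correcting code
    (information-set decoding, count rescaling and threshold-sweep decoding).
    Includes a synthetic sequencing-run generator with realistic per-molbit
    count dispersion for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
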