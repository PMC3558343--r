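Package: tilewave
Title: Wavelet-Based Functional Models for Tiling Array Transcriptome
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probe-level analysis of genome-tiling expression data with a
    wavelet-based functional model. Log2 probe intensities along a
    chromosome are projected onto an orthonormal wavelet basis, effect
    functions for flexible experimental designs (two-group, multi-group
    Helmert, polynomial time-course, circadian Fourier, and custom
    multi-factor designs orthogonalized by QR) are fitted with
    empirical-Bayes shrinkage estimated by marginal maximum likelihood,
    and transcriptionally affected genomic regions are called with a
    Bayesian false discovery rate on posterior effect probabilities.
    Includes a synthetic-data generator with known ground truth, region
    post-processing against gene annotation, and TSV/BED/bedGraph/GFF3
    interchange.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    grDevices,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
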