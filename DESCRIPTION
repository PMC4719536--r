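Package: bacpool
Title: Assembly Support for Pooled BAC Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools supporting BAC-by-BAC genome assembly from pooled,
    indexed Illumina libraries. Provides pair-atomic contaminant and
    clonal read filtering with Table-style pre-processing reports,
    coverage-saturation analysis via with-replacement subsampling and
    local quadratic (LOESS) smoothing, deconvolution of pooled
    assemblies back to source clones by scoring BAC-end-sequence hits
    with an edge-distance-penalised bit score, mate-pair orientation
    quality control and SSPACE-style scaffolding-link construction,
    pool design from clone-overlap metadata, and a fully ground-truthed
    synthetic BAC pool simulator so every stage is testable without
    real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
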