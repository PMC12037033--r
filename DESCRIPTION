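Package: spatac
Title: Spatially Barcoded ATAC-seq Fragments, Copy Number, and Mitochondrial Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing toolkit for spatially barcoded single-end ATAC-seq.
    Transfers corrected spot barcodes and UMIs onto genome alignments by read
    name, removes PCR duplicates with a directional UMI network, builds a
    synthetic paired-end fragments file with per-spot quality metrics (TSS
    enrichment, mitochondrial fraction), constructs sparse spot-by-tile and
    spot-by-gene accessibility matrices, estimates amplicon and ecDNA copy
    number from GC-matched sliding-window background signal, and calls
    spot-resolved mitochondrial variants with a strand-correlation pass filter
    and per-spot heteroplasmy. Ships a synthetic-data generator that emulates
    every input with machine-readable ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
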