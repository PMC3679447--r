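Package: pirnakit
Title: Simulation and Statistics for piRNA Pathway Small-RNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-RNA analytics for the Drosophila piRNA pathway: a seeded
    generative simulator of piRNA/miRNA sequencing libraries with ground
    truth (uni- and dual-strand clusters, 1U-biased primary piRNAs,
    ping-pong pairs with 10-nt 5' overlaps, miRNA anchor populations,
    knockdown perturbations); exact strand-aware mapping of collapsed reads
    onto transposon/cluster/miRNA panels with multi-mapper weighting;
    miRNA-anchored library normalization, signed coverage profiles, length
    histograms and RPKM filtering; ping-pong 5'-overlap signatures with
    z-scores and positional nucleotide bias (1U/10A); control-versus-
    knockdown comparisons; and RNAi-screen sensitivity statistics
    (per-line efficiency, gene-level false-negative model, expression-bin
    phenotype rates, fold-change group tests, pathway-specificity classes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
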