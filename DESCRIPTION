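Package: fourcre
Title: 4C-seq Viewpoint Interaction Calling and Cis-Regulatory Element
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of circularized chromosome conformation capture
    (4C-seq) viewpoint experiments: in-silico NlaIII/DpnII restriction
    digestion and fragment-map filtering, normalization, running-window
    smoothing and binning of per-fragment-end read counts, interaction
    calling against a non-increasing (isotonic) distance-decay background
    with coverage and signal-to-noise criteria, merging of interacting
    fragments into potential cis-regulatory elements (pCREs),
    shared/gained/lost classification across cell lines, permutation-based
    overlap enrichment against ChIP-seq peak sets with Benjamini-Hochberg
    correction, fixed-width rebinning with percentile scores and pairwise
    Pearson correlation, and de novo k-mer over-representation motif
    analysis. Includes a synthetic-data generator (genomes, replicated
    negative-binomial 4C profiles with planted interactions, ChIP peak
    sets with planted overlap) so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
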