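Package: riddscan
Title: Stem-Loop Endomotif Scanning and Analysis of IRE1-Dependent mRNA Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@riddscan.org",
           role = c("aut", "cre"))
Description: Tools for studying the two endoribonuclease modalities of the
    unfolded-protein-response sensor IRE1alpha. Implements a stem-loop
    endomotif scanner that locates CNG|CAGN consensus loops, enumerates the
    best enclosing hairpin within a local flanking window, and classifies
    transcripts as canonical decay substrates (RIDD) or endomotif-lacking
    substrates (RIDDLE); an integrated steady-state/nascent (RNA-seq vs
    GRO-seq) decay-candidate filter chain with TMM normalization and
    moderated differential statistics; a cleavage-fragment 3'-end mapper
    with GC-dinucleotide enrichment testing and hotspot calling; gene-set
    mean Z-score signature scoring with median splits; and seeded synthetic
    data generators that emulate each assay for fully offline testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    edgeR
Suggests:
    limma,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
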