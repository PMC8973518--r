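Package: MARseq
Title: Downstream Analysis of Nuclear Matrix Attachment Region Sequencing Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of MAR-Seq experiments, which map
    nuclear matrix attachment regions (MARs) genome-wide from sequencing peaks.
    Provides interval merging and three-way peak-set (Venn) partitioning,
    chromosome-wise MAR and gene density statistics, chromatin loop-length
    estimation from inter-MAR distances, TSS-distance profiling and
    exonic/intronic/non-genic context classification, scanning of a catalog of
    MAR-associated degenerate and gapped DNA motifs plus the bipartite MAR
    recognition signature (MRS), MISA-style simple sequence repeat detection,
    filtering of transposable-element alignment hits, gene-flank MAR reports,
    pathway joins, and a synthetic-data generator that plants peaks, motifs,
    MRS pairs and SSRs at known positions so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
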