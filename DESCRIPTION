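Package: peaksets
Title: Linking Transcription-Factor ChIP-Seq Peaks to Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of transcription-factor ChIP-seq peak calls
    in relation to gene sets: classification of peak summits into seven
    genomic features (promoter, UTRs, exon, intron, downstream, distal
    intergenic), chromatin-state annotation of summits against a fixed-bin
    15-state segmentation, hypergeometric tests for feature bias of gene-set
    associated peaks, and a bootstrap gene-set peak-count enrichment test
    with skew-normal tail fitting.  Companion expression-side analyses cover
    probe collapsing, pairwise correlation with complete-linkage clustering,
    two-group differential expression with Benjamini-Hochberg correction,
    and directed/undirected gene-set perturbation tests.  A synthetic-data
    module generates annotated genomes, peak sets, segmentations and
    expression matrices with planted structure so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
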