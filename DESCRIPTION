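Package: fibroprog
Title: Multi-Omics Detection of Endocrine-Disruptor-Induced Reprogramming in Myometrial Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for two-condition (EDC-exposed versus vehicle)
    tri-omics profiling of myometrial stem cells: differential gene expression
    on RNA-seq counts at a twofold / FDR 0.05 cutoff, sliding-window G-test
    differential H3K4me3 enrichment with region merging and TSS annotation,
    single-mark chromatin-state segmentation by a binarized-emission hidden
    Markov model with per-state odds-ratio enrichment, RRBS and targeted-panel
    differential CpG methylation at 10/33/50 percentage-point thresholds, and
    per-gene direction-concordance classification across the three layers.
    Includes a seeded synthetic tri-omics generator with planted ground truth
    so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
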