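Package: hifmap
Title: Integration of HIF1a Binding Sites with Chromatin Accessibility and
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for genome-wide integration of
    transcription-factor binding sites (CUT&RUN or ChIP peaks) with gene
    annotation, open chromatin and differential expression. Peaks are assigned
    to nearest-TSS genes, binned by distance, classified by genomic feature and
    flagged for open-chromatin overlap; enrichment is quantified against a
    length-preserving random-placement (shuffle) null with chi-square
    goodness-of-fit tests and Bonferroni correction; gene-level binding is
    joined with a differential-expression table to test binding-DEG
    association overall and per distance stratum, compare fold-change
    magnitudes, and call distance-bounded target genes. Includes an IUPAC
    consensus-motif enrichment check and a fully seeded synthetic-data
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    methods,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
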