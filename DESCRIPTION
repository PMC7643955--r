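Package: methexpr
Title: Single-Cell Methylome and Transcriptome Integration for Oocyte Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A workbench for integrative analysis of sparse single-cell
    bisulfite data and single-cell expression data across oocyte maturation
    stages (GV, MI, MII). Implements context-specific (CpG, CHG, CHH)
    differentially methylated region calling with a 3 kb / 600 bp sliding
    window and Fisher-exact window tests, genomic classification of regions
    against gene annotation and repeat/accessibility tracks, FPKM/TPM
    normalization with negative-binomial differential expression, PWM motif
    scanning inside regions, transcription-factor triangulation against
    binding-partner lists, and hypergeometric gene-set enrichment. Ships a
    synthetic-data generator with planted ground truth (DMRs, DEGs, motif
    occurrences) so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
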