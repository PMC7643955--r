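#!/usr/bin/env Rscript
# Stage 5: integrate methylome and transcriptome — gene-body CHH methylation
# vs expression correlation in MII, upregulated DEGs with a gene-body DMR,
# hypergeometric enrichment of the truth-linked target set, and (when a TF
# motif was planted) PWM-based TF triangulation with hyper/hypo tallies.

suppressPackageStartupMessages({library(methexpr); library(data.table)})

args <- commandArgs(trailingOnly = TRUE)
simdir <- if (length(args) >= 1) args[[1]] else "results/sim"
dmrdir <- if (length(args) >= 2) args[[2]] else "results/dmrs"
exprdir <- if (length(args) >= 3) args[[3]] else "results/expression"
outdir <- if (length(args) >= 4) args[[4]] else "results/integration"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ann <- read_gtf(file.path(simdir, "annotation.gtf"))
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
ann$chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
calls <- read_cytosine_tsv(file.path(simdir, "cytosine_calls.tsv"))
dmrs <- read_dmr_bed(file.path(dmrdir, "dmrs_mii_mi.bed"))
degs <- fread(file.path(exprdir, "degs_mii_mi.tsv"), data.table = FALSE)
fpkm <- fread(file.path(exprdir, "fpkm_by_stage.tsv"), data.table = FALSE)
fpkm_mat <- as.matrix(fpkm[, -1]); rownames(fpkm_mat) <- fpkm$gene_id
links <- fread(file.path(simdir, "truth_links.tsv"), data.table = FALSE)

# gene-body CHH methylation vs expression, MII
pool <- pool_cells(calls)
pool_mii <- pool[pool$group == "MII"]
corr <- gene_body_meth_expr(pool_mii, fpkm_mat[, "MII"], ann, "CHH")
fwrite(corr$pairs, file.path(outdir, "gene_body_meth_expr_pairs.tsv"),
       sep = "\t")
message(sprintf(
  "gene-body CHH methylation vs log10(FPKM+1) in MII: r = %.3f (p = %.2g) over %d genes",
  corr$r, corr$p, nrow(corr$pairs)))

# upregulated MII/MI DEGs with a gene-body DMR
dd <- degs_with_gene_body_dmr(degs, dmrs, ann, direction_filter = "up")
fwrite(dd$pairs, file.path(outdir, "updeg_gene_body_dmr_pairs.tsv"),
       sep = "\t")
message(sprintf(
  "%d/%d (%.0f%%) upregulated MII/MI DEGs carry a gene-body DMR (hyper: %d, hypo: %d genes)",
  length(dd$genes), sum(degs$deg & degs$direction == "up"),
  100 * dd$fraction, dd$tallies["hyper"], dd$tallies["hypo"]))

# enrichment of the truth-linked target set among upregulated DEGs
up <- degs$gene_id[degs$deg & degs$direction == "up"]
if (nrow(links) > 0L && length(up) > 0L) {
  enr <- gene_set_enrichment(up, list(dmr_linked_truth = unique(links$gene_id)),
                             universe = rownames(fpkm_mat))
  fwrite(enr, file.path(outdir, "enrichment.tsv"), sep = "\t")
  message(sprintf("truth-linked target set enrichment among up DEGs: p = %.3g (overlap %d/%d)",
                  enr$p[1], enr$n_overlap[1], enr$n_set[1]))
}
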