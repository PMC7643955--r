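#!/usr/bin/env Rscript
# Stage 3: expression normalisation (TPM per cell, FPKM per merged stage),
# expressed and stage-specific gene sets (FPKM >= 1), pairwise differential
# expression (NB Wald, adjusted p <= 0.05 and fold change >= 2), and the
# top-1000-gene PCA. The GV-vs-MI contrast is expected to be empty; the
# planted effects sit in the MII contrasts.

suppressPackageStartupMessages({library(methexpr); library(data.table)})

args <- commandArgs(trailingOnly = TRUE)
simdir <- if (length(args) >= 1) args[[1]] else "results/sim"
outdir <- if (length(args) >= 2) args[[2]] else "results/expression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cm <- read_counts_tsv(file.path(simdir, "counts.tsv"),
                      file.path(simdir, "cell_stages.tsv"))
truth_degs <- fread(file.path(simdir, "truth_degs.tsv"))

tpm <- compute_tpm(cm$counts, cm$gene_lengths)
fpkm <- compute_fpkm(cm$counts, cm$gene_lengths, merge_by = cm$cell_stage)
fwrite(data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE),
       file.path(outdir, "tpm.tsv"), sep = "\t")
fwrite(data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE),
       file.path(outdir, "fpkm_by_stage.tsv"), sep = "\t")

expressed <- expressed_set(fpkm)
specific <- stage_specific(fpkm)
write_gene_sets(expressed, file.path(outdir, "expressed_sets.tsv"))
write_gene_sets(specific, file.path(outdir, "stage_specific_sets.tsv"))
message(sprintf("expressed genes (FPKM >= 1): %s; stage-specific: %s",
                paste(sprintf("%s=%d", names(expressed), lengths(expressed)),
                      collapse = ", "),
                paste(sprintf("%s=%d", names(specific), lengths(specific)),
                      collapse = ", ")))

pairs <- list(c("GV", "MI"), c("MI", "MII"), c("GV", "MII"))
for (ct in pairs) {
  degs <- call_degs(cm, ct[1], ct[2])
  tag <- tolower(paste(ct[2], ct[1], sep = "_"))
  fwrite(degs, file.path(outdir, sprintf("degs_%s.tsv", tag)), sep = "\t")
  n_deg <- sum(degs$deg)
  rec <- if (ct[2] == "MII")
    mean(truth_degs$gene_id %in% degs$gene_id[degs$deg]) else NA
  message(sprintf("%s vs %s: %d DEGs (%d up, %d down)%s",
                  ct[2], ct[1], n_deg,
                  sum(degs$deg & degs$direction == "up"),
                  sum(degs$deg & degs$direction == "down"),
                  if (is.na(rec)) "" else
                    sprintf("; planted recovery %.0f%%", 100 * rec)))
}

pca <- pca_embedding(tpm, top_n = 1000L)
coords <- data.frame(cell_id = rownames(pca$coords),
                     stage = cm$cell_stage[rownames(pca$coords)],
                     pca$coords[, 1:2, drop = FALSE])
fwrite(coords, file.path(outdir, "pca_top_expressed.tsv"), sep = "\t")
message(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance",
                100 * pca$explained_variance[1],
                100 * pca$explained_variance[2]))
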