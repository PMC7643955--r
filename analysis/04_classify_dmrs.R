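#!/usr/bin/env Rscript
# Stage 4: classify the MII/MI DMRs against the gene annotation (promoter >
# 5'UTR > 3'UTR > exon > intron > distal), flag distal DMRs (no promoter /
# exon / UTR overlap), and compute repeat and accessibility overlap
# fractions per context and direction.

suppressPackageStartupMessages({library(methexpr); library(data.table)})

args <- commandArgs(trailingOnly = TRUE)
simdir <- if (length(args) >= 1) args[[1]] else "results/sim"
dmrdir <- if (length(args) >= 2) args[[2]] else "results/dmrs"
outdir <- if (length(args) >= 3) args[[3]] else "results/classified"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ann <- read_gtf(file.path(simdir, "annotation.gtf"))
ann$repeats <- as.data.frame(read_bed(file.path(simdir, "repeats.bed"),
                                      col_names = "family"))
ann$accessible <- as.data.frame(read_bed(file.path(simdir,
                                                   "accessible.bed")))
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
ann$chrom_lengths <- setNames(Biostrings::width(genome), names(genome))

dmrs <- read_dmr_bed(file.path(dmrdir, "dmrs_mii_mi.bed"))
cls <- classify_dmrs(dmrs, ann)
write_bed(cls$dmrs, file.path(outdir, "dmrs_classified.bed"))
fwrite(cls$summary, file.path(outdir, "dmr_summary.tsv"), sep = "\t")

noncpg <- cls$dmrs[cls$dmrs$context %in% c("CHG", "CHH"), , drop = FALSE]
message(sprintf(
  "%d MII/MI DMRs: %.0f%% distal; %.0f%% of non-CpG DMRs in repeats; feature breakdown: %s",
  nrow(cls$dmrs), 100 * mean(cls$dmrs$distal),
  if (nrow(noncpg)) 100 * mean(noncpg$in_repeat) else NA,
  paste(names(table(cls$dmrs$feature)), table(cls$dmrs$feature),
        sep = "=", collapse = ", ")))

# nearest genes of distal hypermethylated non-CpG DMRs that sit in LINE1
line1 <- ann$repeats[ann$repeats$family == "LINE1", , drop = FALSE]
sel <- noncpg[noncpg$distal & noncpg$direction == "hyper", , drop = FALSE]
if (nrow(sel) > 0L) {
  sel <- sel[overlaps_any <- vapply(seq_len(nrow(sel)), function(i) {
    any(line1$chrom == sel$chrom[i] & line1$start < sel$end[i] &
          sel$start[i] < line1$end)
  }, logical(1)), , drop = FALSE]
}
if (nrow(sel) > 0L) {
  ng <- nearest_gene(sel, ann, max_dist = 100000L)
  out <- cbind(sel[, c("chrom", "start", "end", "context")], ng)
  fwrite(out, file.path(outdir, "line1_dmr_nearest_genes.tsv"), sep = "\t")
  message(sprintf("%d LINE1-resident distal hyper non-CpG DMRs; %d assigned a nearest gene within 100 kb",
                  nrow(sel), sum(!is.na(ng$gene_id))))
} else {
  message("no LINE1-resident distal hyper non-CpG DMRs in this run")
}
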