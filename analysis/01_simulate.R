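#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — genome, annotation, per-cell
# methylomes (GV/MI/MII) with planted non-CpG DMRs, lambda spike-ins, and a
# count matrix with planted MII-only DEGs. Writes everything as plain text
# under results/sim/.

suppressPackageStartupMessages(library(methexpr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
outdir <- if (length(args) >= 2) args[[2]] else "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

ann <- simulate_annotation(cfg)
met <- simulate_methylome(ann, cfg)
trx <- simulate_transcriptome(met$annotation, cfg, met$truth)
ann <- met$annotation
truth <- trx$truth

Biostrings::writeXStringSet(ann$genome, file.path(outdir, "genome.fa"))
write_gtf(ann, file.path(outdir, "annotation.gtf"))
write_bed(ann$repeats, file.path(outdir, "repeats.bed"))
write_bed(ann$accessible, file.path(outdir, "accessible.bed"))
write_cytosine_tsv(met$calls, file.path(outdir, "cytosine_calls.tsv"))
write_cytosine_tsv(met$spikein, file.path(outdir, "lambda_spikein.tsv"))
write_counts_tsv(trx$counts, file.path(outdir, "counts.tsv"),
                 file.path(outdir, "cell_stages.tsv"))
write_bed(truth$planted_dmrs, file.path(outdir, "truth_dmrs.bed"))
data.table::fwrite(truth$planted_degs, file.path(outdir, "truth_degs.tsv"),
                   sep = "\t")
data.table::fwrite(truth$dmr_deg_links, file.path(outdir, "truth_links.tsv"),
                   sep = "\t")

qc <- conversion_qc(met$spikein)
data.table::fwrite(qc, file.path(outdir, "conversion_qc.tsv"), sep = "\t")

message(sprintf(
  "simulated %d cells x %d cytosine sites (%.2fM calls), %d planted DMRs (%d in repeats), %d planted DEGs (%d DMR-linked)",
  length(unique(met$calls$cell_id)),
  nrow(unique(met$calls[, c("chrom", "pos", "strand")])),
  nrow(met$calls) / 1e6, nrow(truth$planted_dmrs),
  sum(truth$planted_dmrs$in_repeat), nrow(truth$planted_degs),
  nrow(truth$dmr_deg_links)))
message(sprintf("bisulfite conversion efficiency %.4f (all libraries pass >0.98: %s)",
                conversion_efficiency(met$spikein), all(qc$pass)))
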