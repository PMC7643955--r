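#!/usr/bin/env Rscript
# Stage 2: call context-specific DMRs (3 kb windows, 600 bp step, Fisher
# exact + BH, |delta| >= 0.1) for the MII/MI and MII/GV contrasts from the
# cytosine calls written by stage 1. Writes BED6+ per contrast plus a
# planted-DMR recovery table.

suppressPackageStartupMessages({library(methexpr); library(data.table)})

args <- commandArgs(trailingOnly = TRUE)
simdir <- if (length(args) >= 1) args[[1]] else "results/sim"
outdir <- if (length(args) >= 2) args[[2]] else "results/dmrs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

calls <- read_cytosine_tsv(file.path(simdir, "cytosine_calls.tsv"))
ann <- read_gtf(file.path(simdir, "annotation.gtf"))
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
# truth BED extra columns follow the truth_dmrs data frame (dmr_id first)
truth <- read_bed(file.path(simdir, "truth_dmrs.bed"),
                  col_names = c("dmr_id", "context", "direction", "effect",
                                "in_repeat"))

contrasts <- list(c("MI", "MII"), c("GV", "MII"))
for (ct in contrasts) {
  ca <- calls[calls$stage == ct[1]]
  cb <- calls[calls$stage == ct[2]]
  dmrs <- do.call(rbind, lapply(c("CpG", "CHG", "CHH"), function(ctx) {
    call_dmrs(ca, cb, ctx, chrom_lengths)
  }))
  tag <- tolower(paste(ct[2], ct[1], sep = "_"))
  write_dmr_bed(dmrs, file.path(outdir, sprintf("dmrs_%s.bed", tag)))
  # recovery vs planted truth (planted DMRs are non-CpG, hyper in MII)
  rec <- vapply(seq_len(nrow(truth)), function(i) {
    any(dmrs$chrom == truth$chrom[i] & dmrs$context == truth$context[i] &
          dmrs$direction == truth$direction[i] &
          dmrs$start < truth$end[i] & truth$start[i] < dmrs$end)
  }, logical(1))
  message(sprintf(
    "%s/%s: %d DMRs (%d hyper, %d hypo); planted recovery %d/%d (%.0f%%)",
    ct[2], ct[1], nrow(dmrs), sum(dmrs$direction == "hyper"),
    sum(dmrs$direction == "hypo"), sum(rec), nrow(truth),
    100 * mean(rec)))
}
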