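#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The defaults describe a small three-stage oocyte-maturation experiment:
#' CpG methylation is stage-invariant while mean non-CpG methylation doubles
#' from the immature stages (GV, MI) to the mature MII stage; differential
#' non-CpG methylation is planted as 3 kb regions lying preferentially inside
#' repeat elements; differential expression is planted only in the MII stage
#' so the GV-vs-MI contrast is null by construction.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes number of genes to place, non-overlapping.
#' @param n_cells_per_stage cells simulated per stage.
#' @param stages ordered stage labels, immature to mature.
#' @param cpg_mean mean CpG methylation fraction, all stages.
#' @param noncpg_mean_immature mean CHG/CHH methylation in GV and MI.
#' @param noncpg_mean_mature mean CHG/CHH methylation in MII; must exceed
#'   `noncpg_mean_immature`.
#' @param coverage_rate expected reads per cytosine per cell (Poisson mean).
#' @param n_planted_dmrs number of planted 3 kb non-CpG DMRs (hyper in MII).
#' @param dmr_effect methylation-fraction increase inside planted DMRs
#'   (applied to the MII stage; clamped at 1 with a warning).
#' @param dmr_width width of planted DMRs in bp; equal to the caller's
#'   window so a single window fully contains each planted region.
#' @param frac_dmr_in_repeats fraction of planted DMRs placed inside repeat
#'   intervals.
#' @param n_planted_degs number of planted DEGs (MII vs the immature stages).
#' @param deg_log2fc_range length-2 interval for |log2 fold change| of
#'   planted DEGs.
#' @param frac_dmr_genes_up fraction of genes whose body overlaps a planted
#'   DMR that receive a positive log2FC in MII (recorded as DMR-DEG links).
#' @param nb_dispersion negative-binomial dispersion shared across genes.
#' @param mean_log_expression mean of log gene baseline expression
#'   (log-normal baseline means).
#' @param sd_log_expression sd of log gene baseline expression.
#' @param gene_length_range length-2 range of gene span lengths in bp.
#' @param repeat_fraction target fraction of the genome covered by the
#'   repeat track.
#' @param accessible_fraction target fraction covered by the accessibility
#'   track.
#' @param conversion_failure_rate true bisulfite conversion-failure rate used
#'   for the lambda spike-in table.
#' @param n_spikein_sites number of lambda spike-in cytosines.
#' @param spikein_coverage mean coverage per spike-in site.
#' @param cell_meth_sd per-cell logit-scale jitter of site methylation means
#'   (cell-to-cell variance is not pinned down by the study; default 0).
#' @param tf_motif optional DNA consensus embedded into planted DMRs (for
#'   TF-triangulation fixtures); `NULL` to disable.
#' @param tf_motif_frac fraction of planted DMRs that receive the motif.
#' @param seed integer seed; a fixed seed makes all outputs reproducible.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 200000L,
                       n_genes = 80L,
                       n_cells_per_stage = 5L,
                       stages = c("GV", "MI", "MII"),
                       cpg_mean = 0.5,
                       noncpg_mean_immature = 0.025,
                       noncpg_mean_mature = 0.05,
                       coverage_rate = 1,
                       n_planted_dmrs = 15L,
                       dmr_effect = 0.3,
                       dmr_width = 3000L,
                       frac_dmr_in_repeats = 0.9,
                       n_planted_degs = 30L,
                       deg_log2fc_range = c(1, 3),
                       frac_dmr_genes_up = 0.6,
                       nb_dispersion = 0.1,
                       mean_log_expression = log(20),
                       sd_log_expression = 1,
                       gene_length_range = c(1000L, 2500L),
                       repeat_fraction = 0.45,
                       accessible_fraction = 0.3,
                       conversion_failure_rate = 0.005,
                       n_spikein_sites = 2000L,
                       spikein_coverage = 5,
                       cell_meth_sd = 0,
                       tf_motif = NULL,
                       tf_motif_frac = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    n_cells_per_stage = as.integer(n_cells_per_stage),
    stages = as.character(stages), cpg_mean = cpg_mean,
    noncpg_mean_immature = noncpg_mean_immature,
    noncpg_mean_mature = noncpg_mean_mature, coverage_rate = coverage_rate,
    n_planted_dmrs = as.integer(n_planted_dmrs), dmr_effect = dmr_effect,
    dmr_width = as.integer(dmr_width),
    frac_dmr_in_repeats = frac_dmr_in_repeats,
    n_planted_degs = as.integer(n_planted_degs),
    deg_log2fc_range = as.numeric(deg_log2fc_range),
    frac_dmr_genes_up = frac_dmr_genes_up, nb_dispersion = nb_dispersion,
    mean_log_expression = mean_log_expression,
    sd_log_expression = sd_log_expression,
    gene_length_range = as.integer(gene_length_range),
    repeat_fraction = repeat_fraction,
    accessible_fraction = accessible_fraction,
    conversion_failure_rate = conversion_failure_rate,
    n_spikein_sites = as.integer(n_spikein_sites),
    spikein_coverage = spikein_coverage, cell_meth_sd = cell_meth_sd,
    tf_motif = tf_motif, tf_motif_frac = tf_motif_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("cpg_mean", "noncpg_mean_immature", "noncpg_mean_mature",
                   "frac_dmr_in_repeats", "frac_dmr_genes_up",
                   "repeat_fraction", "accessible_fraction",
                   "conversion_failure_rate", "tf_motif_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("sim_config field '%s' must be a fraction in [0, 1]", f))
    }
  }
  if (cfg$noncpg_mean_mature <= cfg$noncpg_mean_immature) {
    stop("noncpg_mean_mature must exceed noncpg_mean_immature ",
         "(non-CpG methylation rises as oocytes mature)")
  }
  if (cfg$n_chroms < 1L || cfg$chrom_length < cfg$dmr_width) {
    stop("chrom_length must be at least dmr_width")
  }
  if (cfg$coverage_rate < 0 || cfg$nb_dispersion <= 0) {
    stop("coverage_rate must be >= 0 and nb_dispersion > 0")
  }
  if (length(cfg$stages) < 2L || anyDuplicated(cfg$stages)) {
    stop("stages must be >= 2 distinct ordered labels")
  }
  if (length(cfg$deg_log2fc_range) != 2L ||
      diff(cfg$deg_log2fc_range) < 0 || cfg$deg_log2fc_range[1] < 0) {
    stop("deg_log2fc_range must be a non-negative increasing interval")
  }
  if (cfg$n_planted_degs > cfg$n_genes) {
    stop("n_planted_degs cannot exceed n_genes")
  }
  if (!is.null(cfg$tf_motif) &&
      !grepl("^[ACGT]+$", cfg$tf_motif)) {
    stop("tf_motif must be an ACGT consensus string")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: %d x %d bp chromosomes, %d genes, %d cells/stage ",
           "(%s)\n  CpG mean %.3f; non-CpG %.3f -> %.3f (immature -> mature)\n",
           "  coverage ~ Poisson(%.2f); %d planted %d bp DMRs (effect %.2f, ",
           "%.0f%% in repeats)\n  %d planted DEGs, |log2FC| in [%.1f, %.1f]; ",
           "NB dispersion %.3f; seed %d\n"),
    x$n_chroms, x$chrom_length, x$n_genes, x$n_cells_per_stage,
    paste(x$stages, collapse = " < "), x$cpg_mean, x$noncpg_mean_immature,
    x$noncpg_mean_mature, x$coverage_rate, x$n_planted_dmrs, x$dmr_width,
    x$dmr_effect, 100 * x$frac_dmr_in_repeats, x$n_planted_degs,
    x$deg_log2fc_range[1], x$deg_log2fc_range[2], x$nb_dispersion, x$seed))
  invisible(x)
}
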