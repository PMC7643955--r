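#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — simulate (annotation, methylome,
#' transcriptome), DMR calling per context for the two maturation contrasts,
#' expression normalisation and differential expression, genomic
#' classification of DMRs, and methylome-transcriptome integration — writing
#' every output as plain text under `outdir` and returning a manifest of
#' parameters and file checksums. Identical config and seed give identical
#' checksums.
#'
#' @param config a [sim_config()] object.
#' @param outdir output directory (created if missing).
#' @param dmr_params list of DMR-caller parameters
#'   (width, step, q_max, delta_min, min_cov).
#' @param contexts contexts to call DMRs for.
#' @return (invisibly) the manifest: list(parameters, files, versions,
#'   results) where `results` holds the in-memory stage outputs.
#' @export
run_pipeline <- function(config, outdir,
                         dmr_params = list(width = 3000L, step = 600L,
                                           q_max = 0.05, delta_min = 0.1,
                                           min_cov = 10),
                         contexts = c("CpG", "CHG", "CHH")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    ann <- simulate_annotation(config)
    met <- simulate_methylome(ann, config)
    trx <- simulate_transcriptome(met$annotation, config, met$truth)
    list(annotation = met$annotation, calls = met$calls,
         spikein = met$spikein, truth = trx$truth, counts = trx$counts)
  })
  Biostrings::writeXStringSet(sim$annotation$genome, pth("genome.fa"))
  write_gtf(sim$annotation, pth("annotation.gtf"))
  write_bed(sim$annotation$repeats, pth("repeats.bed"))
  write_bed(sim$annotation$accessible, pth("accessible.bed"))
  write_cytosine_tsv(sim$calls, pth("cytosine_calls.tsv"))
  write_cytosine_tsv(sim$spikein, pth("lambda_spikein.tsv"))
  write_counts_tsv(sim$counts, pth("counts.tsv"), pth("cell_stages.tsv"))
  write_bed(sim$truth$planted_dmrs, pth("truth_dmrs.bed"))
  data.table::fwrite(sim$truth$planted_degs, pth("truth_degs.tsv"),
                     sep = "\t")

  qc <- conversion_qc(sim$spikein)
  data.table::fwrite(qc, pth("conversion_qc.tsv"), sep = "\t")

  # -- call-dmrs (later vs earlier stage, both maturation contrasts) -------
  stages_ <- config$stages
  n_st <- length(stages_)
  contrasts <- list(c(stages_[n_st - 1L], stages_[n_st]))   # MI -> MII
  if (n_st >= 3L) {
    contrasts <- c(contrasts, list(c(stages_[1L], stages_[n_st])))  # GV -> MII
  }
  dmrs_all <- stage("call-dmrs", {
    out <- list()
    for (ct in contrasts) {
      ca <- sim$calls[sim$calls$stage == ct[1]]
      cb <- sim$calls[sim$calls$stage == ct[2]]
      for (ctx in contexts) {
        d <- do.call(call_dmrs, c(
          list(cells_a = ca, cells_b = cb, context = ctx,
               chrom_lengths = sim$annotation$chrom_lengths), dmr_params))
        if (nrow(d) > 0L) d$contrast <- paste(ct[2], ct[1], sep = "/")
        out[[paste(ct[2], ct[1], ctx, sep = "_")]] <- d
      }
    }
    out
  })
  dmr_main <- do.call(rbind, dmrs_all[grep(
    paste0("^", stages_[n_st], "_", stages_[n_st - 1L]), names(dmrs_all))])
  rownames(dmr_main) <- NULL
  write_dmr_bed(dmr_main, pth("dmrs_mii_mi.bed"))

  # -- expression ----------------------------------------------------------
  expr <- stage("deg", {
    tpm <- compute_tpm(sim$counts$counts, sim$counts$gene_lengths)
    fpkm_stage <- compute_fpkm(sim$counts$counts, sim$counts$gene_lengths,
                               merge_by = sim$counts$cell_stage)
    degs <- list()
    for (i in seq_len(n_st - 1L)) {
      for (j in seq.int(i + 1L, n_st)) {
        key <- paste(stages_[j], stages_[i], sep = "/")
        degs[[key]] <- call_degs(sim$counts, stages_[i], stages_[j])
      }
    }
    list(tpm = tpm, fpkm_stage = fpkm_stage, degs = degs,
         expressed = expressed_set(fpkm_stage),
         specific = stage_specific(fpkm_stage),
         pca = pca_embedding(tpm, top_n = 1000L))
  })
  data.table::fwrite(data.frame(gene_id = rownames(expr$fpkm_stage),
                                expr$fpkm_stage, check.names = FALSE),
                     pth("fpkm_by_stage.tsv"), sep = "\t")
  key_main <- paste(stages_[n_st], stages_[n_st - 1L], sep = "/")
  data.table::fwrite(expr$degs[[key_main]], pth("degs_mii_mi.tsv"),
                     sep = "\t")

  # -- classify ------------------------------------------------------------
  cls <- stage("classify", classify_dmrs(dmr_main, sim$annotation))
  if (nrow(cls$dmrs) > 0L) {
    write_bed(cls$dmrs, pth("dmrs_classified.bed"))
    data.table::fwrite(cls$summary, pth("dmr_summary.tsv"), sep = "\t")
  }

  # -- integrate -----------------------------------------------------------
  integ <- stage("integrate", {
    pool_mii <- pool_cells(sim$calls)
    pool_mii <- pool_mii[pool_mii$group == stages_[n_st]]
    corr <- tryCatch(
      gene_body_meth_expr(pool_mii, expr$fpkm_stage[, stages_[n_st]],
                          sim$annotation, "CHH"),
      error = function(e) NULL)
    dmr_deg <- tryCatch(
      degs_with_gene_body_dmr(expr$degs[[key_main]], dmr_main,
                              sim$annotation, direction_filter = "up"),
      error = function(e) NULL)
    enr <- NULL
    if (nrow(sim$truth$dmr_deg_links) > 0L) {
      up <- expr$degs[[key_main]]
      up <- up$gene_id[up$deg & up$direction == "up"]
      if (length(up) > 0L) {
        enr <- gene_set_enrichment(
          up, list(linked_truth = unique(sim$truth$dmr_deg_links$gene_id)),
          universe = rownames(sim$counts$counts))
      }
    }
    list(gene_body_corr = corr, dmr_deg = dmr_deg, enrichment = enr)
  })
  if (!is.null(integ$gene_body_corr)) {
    data.table::fwrite(integ$gene_body_corr$pairs,
                       pth("gene_body_meth_expr_pairs.tsv"), sep = "\t")
  }

  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    parameters = unclass(config),
    dmr_params = dmr_params,
    files = tools::md5sum(files),
    versions = c(R = R.version.string,
                 methexpr = as.character(utils::packageVersion("methexpr"))),
    results = list(truth = sim$truth, dmrs = dmrs_all, expr = expr,
                   classified = cls, integration = integ,
                   conversion_qc = qc, annotation = sim$annotation,
                   counts = sim$counts, calls = sim$calls)
  )
  invisible(manifest)
}
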