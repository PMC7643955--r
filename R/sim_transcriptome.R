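#' Simulate a per-cell count matrix with planted MII-only DEGs
#'
#' Gene baseline means are log-normal; counts are negative-binomial with a
#' dispersion shared across genes and per-cell library-size factors. Planted
#' differential expression applies only to the mature MII stage: GV and MI
#' share identical means by construction, mirroring the absence of DEGs
#' between the two immature stages. A configurable fraction of genes whose
#' body overlaps a planted DMR receive a positive log2 fold change,
#' emulating the positive gene-body methylation/expression association; those
#' pairs are recorded as `dmr_deg_links` in the truth set.
#'
#' @param annotation a [simulate_annotation()] result (gene set non-empty).
#' @param config a [sim_config()] object.
#' @param truth `truth_set` from [simulate_methylome()] (may have zero
#'   planted DMRs).
#' @return list with `counts` (a `count_matrix`) and `truth` (updated).
#' @export
simulate_transcriptome <- function(annotation, config, truth) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"),
            inherits(truth, "truth_set"))
  if (nrow(annotation$genes) == 0L) {
    stop("simulate_transcriptome requires a non-empty gene set")
  }
  set.seed(config$seed + 2000L)
  genes <- annotation$genes
  n_genes <- nrow(genes)

  base_mu <- rlnorm(n_genes, config$mean_log_expression,
                    config$sd_log_expression)
  names(base_mu) <- genes$gene_id

  # genes whose body (full transcript span) overlaps a planted DMR
  dmr_genes <- character(0)
  link <- data.frame(gene_id = character(), dmr_id = character(),
                     stringsAsFactors = FALSE)
  if (nrow(truth$planted_dmrs) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(genes), as_granges0(truth$planted_dmrs),
      ignore.strand = TRUE)
    if (length(hits) > 0L) {
      link_all <- data.frame(
        gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
        dmr_id = truth$planted_dmrs$dmr_id[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
      dmr_genes <- unique(link_all$gene_id)
      n_link <- round(config$frac_dmr_genes_up * length(dmr_genes))
      linked_genes <- sort(sample(dmr_genes, n_link))
      link <- link_all[link_all$gene_id %in% linked_genes, , drop = FALSE]
    }
  }

  # planted DEGs: linked DMR genes get positive log2FC; the remaining slots
  # are filled from other genes with random sign
  linked_genes <- unique(link$gene_id)
  if (length(linked_genes) > config$n_planted_degs) {
    linked_genes <- linked_genes[seq_len(config$n_planted_degs)]
    link <- link[link$gene_id %in% linked_genes, , drop = FALSE]
  }
  n_free <- config$n_planted_degs - length(linked_genes)
  pool <- setdiff(genes$gene_id, linked_genes)
  free_genes <- if (n_free > 0L) sort(sample(pool, min(n_free, length(pool))))
                else character(0)
  deg_ids <- c(linked_genes, free_genes)
  l2fc <- runif(length(deg_ids), config$deg_log2fc_range[1],
                config$deg_log2fc_range[2])
  sgn <- c(rep(1, length(linked_genes)),
           sample(c(-1, 1), length(free_genes), replace = TRUE))
  l2fc <- l2fc * sgn
  names(l2fc) <- deg_ids

  mature_stage <- config$stages[length(config$stages)]
  cells <- as.vector(outer(seq_len(config$n_cells_per_stage), config$stages,
                           function(i, st) sprintf("%s_%d", st, i)))
  cell_stage <- setNames(rep(config$stages, each = config$n_cells_per_stage),
                         cells)
  sf <- rlnorm(length(cells), 0, 0.15)

  counts <- matrix(0L, nrow = n_genes, ncol = length(cells),
                   dimnames = list(genes$gene_id, cells))
  for (j in seq_along(cells)) {
    mu <- base_mu
    if (cell_stage[j] == mature_stage && length(deg_ids) > 0L) {
      mu[deg_ids] <- mu[deg_ids] * 2^l2fc
    }
    counts[, j] <- rnbinom(n_genes, mu = mu * sf[j],
                           size = 1 / config$nb_dispersion)
  }

  lengths <- exon_union_lengths(annotation)
  cm <- count_matrix(counts, lengths[genes$gene_id], cell_stage)

  truth$planted_degs <- data.frame(gene_id = deg_ids, log2fc = unname(l2fc),
                                   stringsAsFactors = FALSE)
  truth$dmr_deg_links <- link
  list(counts = cm, truth = truth)
}

#' Gene lengths as union-of-exons width
#'
#' The effective length used for FPKM/TPM: total bases covered by at least
#' one exon of the gene.
#'
#' @param annotation a `genome_annotation`.
#' @return named numeric vector of lengths in bp.
#' @export
exon_union_lengths <- function(annotation) {
  ex <- annotation$exons
  if (nrow(ex) == 0L) return(setNames(numeric(0), character(0)))
  out <- vapply(split(ex, ex$gene_id), function(e) {
    m <- merge_intervals(e[, c("chrom", "start", "end")])
    sum(m$end - m$start)
  }, numeric(1))
  out
}

#' Count matrix container
#'
#' @param counts genes x cells matrix of non-negative integers with dimnames.
#' @param gene_lengths named vector of effective gene lengths (bp), positive.
#' @param cell_stage named character vector mapping every cell to one stage.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, cell_stage) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  stopifnot(all(counts >= 0))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("every gene needs a positive effective length")
  }
  cell_stage <- cell_stage[colnames(counts)]
  if (any(is.na(cell_stage))) {
    stop("every cell must be mapped to exactly one stage")
  }
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 cell_stage = cell_stage), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (stages: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_stage), collapse = ", ")))
  invisible(x)
}
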