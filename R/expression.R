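#' TPM normalisation
#'
#' TPM_g = 1e6 * (count_g / length_g) / sum_g(count_g / length_g), per cell.
#' Columns sum to 1e6 except all-zero cells, which stay all-zero (with a
#' warning).
#'
#' @param counts genes x cells count matrix.
#' @param lengths named vector of effective gene lengths in bp (> 0).
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  lengths <- lengths[rownames(counts)]
  stopifnot(all(lengths > 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero cell(s): TPM left at zero for ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' FPKM normalisation
#'
#' FPKM_g = 1e9 * count_g / (length_g * N) with N the total mapped counts of
#' the library. With `merge_by` set, cells of a stage are summed into one
#' merged library first and one FPKM column per stage is returned — the
#' merged-stage expression used for expressed-gene sets and methylation
#' comparisons.
#'
#' @param counts genes x cells count matrix.
#' @param lengths named vector of gene lengths in bp.
#' @param merge_by optional named character vector mapping cells to stages.
#' @return FPKM matrix (per cell, or per stage when merged).
#' @export
compute_fpkm <- function(counts, lengths, merge_by = NULL) {
  lengths <- lengths[rownames(counts)]
  stopifnot(all(lengths > 0))
  if (!is.null(merge_by)) {
    merge_by <- merge_by[colnames(counts)]
    stopifnot(!any(is.na(merge_by)))
    stages <- unique(merge_by)
    counts <- vapply(stages, function(st) {
      rowSums(counts[, merge_by == st, drop = FALSE])
    }, numeric(nrow(counts)))
    colnames(counts) <- stages
  }
  N <- colSums(counts)
  if (any(N == 0)) stop("FPKM undefined: library with zero total counts")
  sweep(counts / lengths, 2, N, "/") * 1e9
}

#' Expressed gene set per stage
#'
#' Genes with merged-stage FPKM at or above the threshold (>= 1 by default,
#' so FPKM exactly 1 is included).
#'
#' @param expr merged-stage FPKM matrix (genes x stages).
#' @param threshold FPKM cutoff (default 1).
#' @return named list of gene-id character vectors, one per stage.
#' @export
expressed_set <- function(expr, threshold = 1) {
  lapply(setNames(colnames(expr), colnames(expr)), function(st) {
    rownames(expr)[expr[, st] >= threshold]
  })
}

#' Stage-specific gene sets
#'
#' A gene is specific to a stage when its FPKM is at or above the threshold
#' there and below the threshold in every other stage; the sets are pairwise
#' disjoint by construction.
#'
#' @inheritParams expressed_set
#' @return named list of gene-id vectors per stage.
#' @export
stage_specific <- function(expr, threshold = 1) {
  stopifnot(ncol(expr) >= 2L)
  on <- expr >= threshold
  lapply(setNames(colnames(expr), colnames(expr)), function(st) {
    others <- setdiff(colnames(expr), st)
    rownames(expr)[on[, st] & rowSums(on[, others, drop = FALSE]) == 0]
  })
}

#' Negative-binomial differential expression (Wald test)
#'
#' Per gene: counts are normalised by median-of-ratios size factors (robust
#' to composition bias when many genes shift one way), a common
#' dispersion is estimated by method of moments across genes, group means
#' are compared with a Wald test on the log mean ratio (delta-method
#' standard errors under Var = mu + alpha mu^2), and p-values are BH-adjusted
#' across tested genes. log2FC uses a pseudo-mean of 0.5 added to both group
#' means so it is always finite; the statistic is referred to a t
#' distribution with n_A + n_B - 2 degrees of freedom. Genes with zero
#' counts in both groups are excluded from the testing universe. DEG flag:
#' q <= q_max and |log2FC| >= min_l2fc ("fold change >= 2" at the defaults).
#'
#' @param cm a [count_matrix()], or a plain counts matrix if `cell_stage`
#'   is given.
#' @param stage_a,stage_b stage labels to contrast (log2FC is B over A).
#' @param q_max adjusted-p threshold (default 0.05).
#' @param min_l2fc minimum |log2FC| (default 1).
#' @param cell_stage optional cell-to-stage map when `cm` is a bare matrix.
#' @return data.frame: gene_id, base_mean_a, base_mean_b, log2fc, p, q,
#'   direction ("up"/"down" in B), deg (logical).
#' @export
call_degs <- function(cm, stage_a, stage_b, q_max = 0.05, min_l2fc = 1,
                      cell_stage = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    cell_stage <- cm$cell_stage
  } else {
    counts <- cm
    stopifnot(!is.null(cell_stage))
    cell_stage <- cell_stage[colnames(counts)]
  }
  ca <- counts[, cell_stage == stage_a, drop = FALSE]
  cb <- counts[, cell_stage == stage_b, drop = FALSE]
  if (ncol(ca) < 2L || ncol(cb) < 2L) {
    stop("call_degs needs >= 2 cells per stage")
  }
  sub <- cbind(ca, cb)
  grp <- rep(c("A", "B"), c(ncol(ca), ncol(cb)))

  # median-of-ratios size factors (robust to composition shifts when many
  # genes move in one direction); total-count fallback for tiny universes
  libsize <- colSums(sub)
  if (any(libsize == 0)) stop("cell with zero total counts")
  loggeo <- rowMeans(log(sub))
  use <- is.finite(loggeo)
  if (sum(use) >= 10L) {
    sf <- apply(sub[use, , drop = FALSE], 2, function(k) {
      exp(median(log(k) - loggeo[use]))
    })
  } else {
    sf <- libsize / exp(mean(log(libsize)))
  }
  sf <- sf / exp(mean(log(sf)))
  y <- sweep(sub, 2, sf, "/")

  keep <- rowSums(sub) > 0
  yk <- y[keep, , drop = FALSE]
  ya <- yk[, grp == "A", drop = FALSE]
  yb <- yk[, grp == "B", drop = FALSE]
  na <- ncol(ya); nb <- ncol(yb)
  mA <- rowMeans(ya); mB <- rowMeans(yb)

  # method-of-moments common dispersion from within-group moments
  pooled_var <- (rowSums((ya - mA)^2) + rowSums((yb - mB)^2)) / (na + nb - 2)
  pooled_mu <- (na * mA + nb * mB) / (na + nb)
  ok <- pooled_mu > 0
  alpha_g <- (pooled_var[ok] - pooled_mu[ok]) / pooled_mu[ok]^2
  alpha <- max(median(alpha_g[is.finite(alpha_g)], na.rm = TRUE), 1e-8)

  l2fc <- log2((mB + 0.5) / (mA + 0.5))
  var_log <- function(mu, n) (mu + alpha * mu^2) / n / (mu + 0.5)^2
  se <- sqrt(var_log(mA, na) + var_log(mB, nb))
  z <- (log(mB + 0.5) - log(mA + 0.5)) / se
  z[se == 0] <- 0
  # t reference with n_A + n_B - 2 df: the plug-in dispersion makes a plain
  # normal reference anti-conservative at single-cell group sizes
  p <- 2 * pt(-abs(z), df = na + nb - 2)
  q <- p.adjust(p, method = "BH")

  res <- data.frame(
    gene_id = rownames(yk), base_mean_a = mA, base_mean_b = mB,
    log2fc = l2fc, p = p, q = q,
    direction = ifelse(l2fc >= 0, "up", "down"),
    deg = q <= q_max & abs(l2fc) >= min_l2fc,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dispersion") <- alpha
  attr(res, "contrast") <- c(A = stage_a, B = stage_b)
  res
}

#' PCA embedding of the top expressed genes
#'
#' Ranks genes by mean expression across cells, keeps the top `top_n`,
#' applies log2(x + 1), centres, and returns per-cell principal-component
#' coordinates with non-increasing explained variance.
#'
#' @param expr genes x cells expression matrix (e.g. TPM).
#' @param top_n number of top expressed genes to use (default 1000; capped
#'   at the number of genes).
#' @return list with `coords` (cells x PCs), `explained_variance`
#'   (fractions), and `genes_used`.
#' @export
pca_embedding <- function(expr, top_n = 1000L) {
  if (ncol(expr) < 2L) stop("pca_embedding needs >= 2 cells")
  stopifnot(top_n >= 1L)
  top_n <- min(top_n, nrow(expr))
  rank_mean <- order(rowMeans(expr), decreasing = TRUE)
  sel <- rownames(expr)[rank_mean[seq_len(top_n)]]
  x <- t(log2(expr[sel, , drop = FALSE] + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, explained_variance = ev, genes_used = sel)
}
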