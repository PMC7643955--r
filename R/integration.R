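#' Build a position weight matrix
#'
#' Either from a 4 x L base-probability matrix (rows A, C, G, T; columns sum
#' to 1) or from an ACGT consensus string, in which case each column puts
#' probability `1 - 3 * eps` on the consensus base.
#'
#' @param id motif identifier (the TF name).
#' @param x probability matrix or consensus string; motif length >= 4.
#' @param background base background probabilities (default uniform).
#' @param eps off-consensus probability when building from a consensus.
#' @return object of class `pwm`: list(id, mat, background).
#' @export
make_pwm <- function(id, x, background = rep(0.25, 4), eps = 0.01) {
  bases <- c("A", "C", "G", "T")
  if (is.character(x) && length(x) == 1L) {
    stopifnot(grepl("^[ACGT]+$", x))
    cons <- strsplit(x, "", fixed = TRUE)[[1]]
    mat <- matrix(eps, 4, length(cons), dimnames = list(bases, NULL))
    mat[cbind(match(cons, bases), seq_along(cons))] <- 1 - 3 * eps
  } else {
    mat <- as.matrix(x)
    rownames(mat) <- bases
  }
  if (ncol(mat) < 4L) stop("PWM length must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1 (tolerance 1e-6)")
  }
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  structure(list(id = id, mat = mat,
                 background = setNames(background, bases)),
            class = "pwm")
}

#' Maximum attainable PWM log-odds score (bits)
#' @param pwm a [make_pwm()] object.
#' @export
pwm_max_score <- function(pwm) {
  lom <- log2(pwm$mat / pwm$background)
  sum(apply(lom, 2, max))
}

#' Scan sequences with a PWM
#'
#' Log-odds scan of both strands: score(w) = sum_i log2(p_i(base) / bg(base))
#' in bits; windows containing N score -Inf. Hits are windows scoring at or
#' above the threshold, which defaults to 0.8 x the maximum attainable score
#' of the PWM. Minus-strand hits are reported in plus-strand coordinates.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param pwm a [make_pwm()] object.
#' @param threshold_bits score threshold; `NULL` for the 0.8 x max default.
#' @return data.frame: motif_id, seqname, start, end (0-based half-open
#'   within the sequence), strand, score.
#' @export
pwm_scan <- function(sequences, pwm, threshold_bits = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(threshold_bits)) threshold_bits <- 0.8 * pwm_max_score(pwm)
  seqs <- if (inherits(sequences, "DNAStringSet")) {
    setNames(as.character(sequences), names(sequences))
  } else sequences
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  lom <- log2(pwm$mat / pwm$background)
  m <- ncol(lom)
  bases <- c("A", "C", "G", "T")

  scan_one <- function(s) {
    L <- nchar(s)
    if (L < m) return(numeric(0))
    code <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], bases)
    n_pos <- L - m + 1L
    sc <- numeric(n_pos)
    for (i in seq_len(m)) {
      v <- lom[cbind(code[seq.int(i, i + n_pos - 1L)], i)]
      v[is.na(v)] <- -Inf
      sc <- sc + v
    }
    sc
  }

  hits <- list()
  for (nm in names(seqs)) {
    s <- toupper(seqs[[nm]])
    L <- nchar(s)
    fw <- scan_one(s)
    idx <- which(fw >= threshold_bits)
    if (length(idx)) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = pwm$id, seqname = nm, start = idx - 1L,
        end = idx - 1L + m, strand = "+", score = fw[idx],
        stringsAsFactors = FALSE)
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("N", "N", s))))
    rv <- scan_one(rc)
    idx <- which(rv >= threshold_bits)
    if (length(idx)) {
      # position p (1-based) on the reverse strand covers plus-strand
      # bases [L - p - m + 1, L - p + 1) in 0-based half-open coordinates
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = pwm$id, seqname = nm, start = L - (idx - 1L) - m,
        end = L - (idx - 1L), strand = "-", score = rv[idx],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(motif_id = character(), seqname = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract region sequences from a genome
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @return named character vector, one sequence per region (names
#'   "chrom:start-end").
#' @export
region_sequences <- function(genome, regions) {
  if (nrow(regions) == 0L) return(setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, character(1))
  names(out) <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                        regions$end)
  out
}

#' Gene-body methylation vs expression correlation
#'
#' For every gene with at least `min_cov` pooled coverage in its body (full
#' transcript span, one context), pairs the weighted methylation level with
#' log10(FPKM + 1) of the same stage and reports the Pearson correlation.
#'
#' @param pool pooled profile of one stage ([pool_cells()] output filtered to
#'   one group, or any table with chrom, pos, context, meth, total).
#' @param expr named numeric vector of merged-stage FPKM per gene.
#' @param annotation a `genome_annotation`.
#' @param context context label.
#' @param min_cov minimum pooled body coverage (default 10).
#' @return list: `pairs` (gene_id, meth, log_expr, coverage), `r`, `p`.
#' @export
gene_body_meth_expr <- function(pool, expr, annotation, context,
                                min_cov = 10) {
  ctx <- context_label(context)
  pool <- data.table::as.data.table(pool)
  pool <- pool[which(pool$context == ctx)]
  g <- annotation$genes
  if (nrow(pool) > 0L && nrow(g) > 0L) {
    sgr <- GenomicRanges::GRanges(pool$chrom,
                                  IRanges::IRanges(pool$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(as_granges0(g), sgr,
                                        ignore.strand = TRUE)
    agg <- data.table::data.table(
      gene_id = g$gene_id[S4Vectors::queryHits(hits)],
      meth = pool$meth[S4Vectors::subjectHits(hits)],
      total = pool$total[S4Vectors::subjectHits(hits)])
    agg <- agg[, .(meth = sum(meth), total = sum(total)), by = gene_id]
  } else {
    agg <- data.table::data.table(gene_id = character(), meth = numeric(),
                                  total = numeric())
  }
  agg <- agg[agg$total >= min_cov & agg$gene_id %in% names(expr)]
  pairs <- data.frame(
    gene_id = agg$gene_id,
    meth = agg$meth / agg$total,
    log_expr = log10(expr[agg$gene_id] + 1),
    coverage = agg$total,
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(pairs) < 3L) {
    stop("gene_body_meth_expr: fewer than 3 genes with sufficient body ",
         "coverage; correlation undefined")
  }
  if (var(pairs$meth) == 0 || var(pairs$log_expr) == 0) {
    warning("degenerate input: zero variance; correlation undefined")
    return(list(pairs = pairs, r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(pairs$meth, pairs$log_expr, method = "pearson")
  list(pairs = pairs, r = unname(ct$estimate), p = ct$p.value)
}

#' DEGs with a DMR in their gene body
#'
#' Among DEGs passing the direction filter, finds the genes whose body (full
#' transcript span) overlaps at least one DMR, the fraction of the filtered
#' DEGs they represent, and per-direction tallies of the overlapping DMRs.
#'
#' @param degs [call_degs()] output.
#' @param dmrs [call_dmrs()] output (or several contexts row-bound).
#' @param annotation a `genome_annotation`.
#' @param direction_filter "up", "down" or NULL (all DEGs).
#' @param context optional DMR context restriction.
#' @return list: `genes` (gene-id vector), `fraction` of filtered DEGs,
#'   `tallies` (genes with >= 1 hyper / hypo body DMR), `pairs`
#'   (gene_id x dmr rows).
#' @export
degs_with_gene_body_dmr <- function(degs, dmrs, annotation,
                                    direction_filter = "up",
                                    context = NULL) {
  sel <- degs[degs$deg, , drop = FALSE]
  if (!is.null(direction_filter)) {
    sel <- sel[sel$direction == direction_filter, , drop = FALSE]
  }
  if (nrow(sel) == 0L) {
    stop("degs_with_gene_body_dmr: no DEGs pass the filter; ",
         "fraction undefined")
  }
  if (!is.null(context)) {
    dmrs <- dmrs[dmrs$context == context_label(context), , drop = FALSE]
  }
  g <- annotation$genes
  g <- g[g$gene_id %in% sel$gene_id, , drop = FALSE]
  pairs <- data.frame(gene_id = character(), dmr_chrom = character(),
                      dmr_start = integer(), dmr_end = integer(),
                      dmr_direction = character(), stringsAsFactors = FALSE)
  if (nrow(dmrs) > 0L && nrow(g) > 0L) {
    hits <- GenomicRanges::findOverlaps(as_granges0(g), as_granges0(dmrs),
                                        ignore.strand = TRUE)
    if (length(hits) > 0L) {
      pairs <- data.frame(
        gene_id = g$gene_id[S4Vectors::queryHits(hits)],
        dmr_chrom = dmrs$chrom[S4Vectors::subjectHits(hits)],
        dmr_start = dmrs$start[S4Vectors::subjectHits(hits)],
        dmr_end = dmrs$end[S4Vectors::subjectHits(hits)],
        dmr_direction = dmrs$direction[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
    }
  }
  genes <- sort(unique(pairs$gene_id))
  tallies <- c(
    hyper = length(unique(pairs$gene_id[pairs$dmr_direction == "hyper"])),
    hypo = length(unique(pairs$gene_id[pairs$dmr_direction == "hypo"])))
  list(genes = genes, fraction = length(genes) / nrow(sel),
       tallies = tallies, pairs = pairs)
}

#' Triangulate candidate regulatory transcription factors
#'
#' Combines three lines of evidence per TF: expressed (FPKM >= `fpkm_min` in
#' any of the given stages), a known binding partner of the de novo
#' methyltransferase (user-supplied partner list), and at least one PWM hit
#' of its motif inside a DMR. Triangulated TFs are the conjunction of the
#' three flags; a distal-DMR motif flag and an upregulated-DEG flag are
#' reported alongside. TFs without a PWM get an NA motif flag and are
#' excluded from triangulation (with a message).
#'
#' @param expr merged-stage FPKM matrix (genes x stages).
#' @param partner_list character vector of partner TF ids (gene ids).
#' @param pwm_set named list of [make_pwm()] objects (names = TF ids).
#' @param dmrs DMR data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param degs optional [call_degs()] output for the upregulated flag.
#' @param annotation optional `genome_annotation` for the distal-DMR flag.
#' @param stages stage columns that count as "expressed" (default MI, MII).
#' @param fpkm_min expression threshold (default 1).
#' @param threshold_bits PWM score threshold (NULL = 0.8 x max).
#' @return data.frame: tf, expressed, partner, has_pwm, motif_in_dmr,
#'   motif_in_distal_dmr, upregulated, triangulated.
#' @export
tf_triangulate <- function(expr, partner_list, pwm_set, dmrs, genome,
                           degs = NULL, annotation = NULL,
                           stages = c("MI", "MII"), fpkm_min = 1,
                           threshold_bits = NULL) {
  tfs <- sort(union(partner_list, names(pwm_set)))
  stages <- intersect(stages, colnames(expr))
  dmr_seqs <- region_sequences(genome, dmrs)
  distal_names <- character(0)
  if (!is.null(annotation) && nrow(dmrs) > 0L) {
    distal_names <- names(dmr_seqs)[is_distal(dmrs, annotation)]
  }
  rows <- lapply(tfs, function(tf) {
    expressed <- tf %in% rownames(expr) &&
      any(expr[tf, stages] >= fpkm_min)
    partner <- tf %in% partner_list
    has_pwm <- tf %in% names(pwm_set)
    motif_in_dmr <- NA
    motif_in_distal <- NA
    if (has_pwm && length(dmr_seqs) > 0L) {
      h <- pwm_scan(dmr_seqs, pwm_set[[tf]], threshold_bits)
      motif_in_dmr <- nrow(h) > 0L
      motif_in_distal <- any(h$seqname %in% distal_names)
    } else if (has_pwm) {
      motif_in_dmr <- FALSE
      motif_in_distal <- FALSE
    }
    upregulated <- if (is.null(degs)) NA else {
      any(degs$gene_id == tf & degs$deg & degs$direction == "up")
    }
    data.frame(tf = tf, expressed = expressed, partner = partner,
               has_pwm = has_pwm, motif_in_dmr = motif_in_dmr,
               motif_in_distal_dmr = motif_in_distal,
               upregulated = upregulated,
               triangulated = isTRUE(expressed) && partner &&
                 isTRUE(motif_in_dmr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$has_pwm)) {
    message("tf_triangulate: no PWM for ",
            paste(out$tf[!out$has_pwm], collapse = ", "),
            "; excluded from triangulation")
  }
  out
}

#' Direction tally of a TF's motif-bearing gene-body DMRs
#'
#' Among the supplied target genes, finds those whose gene body overlaps a
#' DMR containing at least one hit of the TF's motif, and counts how many of
#' those genes have a hypermethylated such DMR.
#'
#' @param target_genes character vector of target gene ids.
#' @param dmrs DMR data.frame.
#' @param annotation a `genome_annotation`.
#' @param pwm the TF's [make_pwm()] object.
#' @param genome named [Biostrings::DNAStringSet].
#' @param threshold_bits PWM score threshold (NULL = 0.8 x max).
#' @return list: n_with_motif_dmr, n_hyper, genes (data.frame gene_id,
#'   hyper).
#' @export
tf_target_direction_tally <- function(target_genes, dmrs, annotation, pwm,
                                      genome, threshold_bits = NULL) {
  empty <- list(n_with_motif_dmr = 0L, n_hyper = 0L,
                genes = data.frame(gene_id = character(), hyper = logical(),
                                   stringsAsFactors = FALSE))
  g <- annotation$genes
  g <- g[g$gene_id %in% target_genes, , drop = FALSE]
  if (nrow(g) == 0L || nrow(dmrs) == 0L) return(empty)
  seqs <- region_sequences(genome, dmrs)
  hits <- pwm_scan(seqs, pwm, threshold_bits)
  with_hit <- names(seqs) %in% hits$seqname
  dmrs_hit <- dmrs[with_hit, , drop = FALSE]
  if (nrow(dmrs_hit) == 0L) return(empty)
  ov <- GenomicRanges::findOverlaps(as_granges0(g), as_granges0(dmrs_hit),
                                    ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty)
  tab <- data.frame(
    gene_id = g$gene_id[S4Vectors::queryHits(ov)],
    direction = dmrs_hit$direction[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  per_gene <- vapply(split(tab$direction, tab$gene_id),
                     function(d) any(d == "hyper"), logical(1))
  genes <- data.frame(gene_id = names(per_gene), hyper = unname(per_gene),
                      stringsAsFactors = FALSE)
  list(n_with_motif_dmr = nrow(genes), n_hyper = sum(genes$hyper),
       genes = genes)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric p-value per target set (probability of an
#' overlap at least as large as observed when drawing |query| genes from the
#' universe), BH-adjusted across sets. A transparent replacement for
#' database-backed TF-target enrichment services over user-supplied sets.
#'
#' @param query_genes character vector, subset of `universe`.
#' @param target_sets named list of character vectors, each a subset of
#'   `universe`.
#' @param universe character vector of all eligible genes.
#' @return data.frame: set, n_set, n_query, n_overlap, p, q.
#' @export
gene_set_enrichment <- function(query_genes, target_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(target_sets), function(nm) {
    set <- unique(intersect(target_sets[[nm]], universe))
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_query = n, n_overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
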