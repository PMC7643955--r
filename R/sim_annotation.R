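#' Simulate a genome annotation
#'
#' Generates a random genome sequence, a set of non-overlapping genes with
#' strand, exon/intron structure and UTRs, a repeat track (with family
#' labels, LINE1 among them) covering a configurable genome fraction, and an
#' accessibility track. All coordinates are 0-based half-open.
#'
#' @param config a [sim_config()] object.
#' @return object of class `genome_annotation`: list with elements `genes`
#'   (gene_id, chrom, strand, start, end, tss), `exons`, `utr5`, `utr3`
#'   (gene_id, chrom, start, end), `repeats` (chrom, start, end, family),
#'   `accessible` (chrom, start, end), `chrom_lengths` (named integer) and
#'   `genome` ([Biostrings::DNAStringSet]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  genes <- place_genes(config, chroms)
  structure_tabs <- build_gene_structures(genes)

  repeats <- place_track(chrom_lengths, config$repeat_fraction,
                         len_range = c(2000L, 7000L))
  if (nrow(repeats) > 0L) {
    repeats$family <- sample(c("LINE1", "Alu", "LTR", "LINE2", "DNA"),
                             nrow(repeats), replace = TRUE,
                             prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
  } else {
    repeats$family <- character(0)
  }
  accessible <- place_track(chrom_lengths, config$accessible_fraction,
                            len_range = c(500L, 2000L))

  structure(list(
    genes = genes,
    exons = structure_tabs$exons,
    utr5 = structure_tabs$utr5,
    utr3 = structure_tabs$utr3,
    repeats = repeats,
    accessible = accessible,
    chrom_lengths = chrom_lengths,
    genome = genome
  ), class = "genome_annotation")
}

# Non-overlapping placement by random gap allocation: gene lengths are drawn
# first; free space is split into random gaps so placement always succeeds
# when the genes fit at all.
place_genes <- function(config, chroms) {
  n <- config$n_genes
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), tss = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  per_chrom <- tabulate(sample(rep_len(seq_along(chroms), n)),
                        nbins = length(chroms))
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) { out[[ci]] <- empty; next }
    lens <- sample(seq(config$gene_length_range[1],
                       config$gene_length_range[2]), k, replace = TRUE)
    free <- config$chrom_length - sum(lens)
    if (free < 0L) {
      stop(sprintf(
        "cannot place %d non-overlapping genes on a %d bp chromosome: gene density %.2f exceeds 1",
        k, config$chrom_length, sum(lens) / config$chrom_length))
    }
    cuts <- sort(runif(k))
    gaps <- floor(diff(c(0, cuts, 1)) * free)
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
    out[[ci]] <- data.frame(
      gene_id = NA_character_, chrom = chroms[ci],
      strand = sample(c("+", "-"), k, replace = TRUE),
      start = as.integer(starts), end = as.integer(starts + lens),
      tss = NA_integer_, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  rownames(genes) <- NULL
  genes
}

# 1-3 exons per gene; 5'UTR is the outer slice of the first exon in
# transcription order, 3'UTR the outer slice of the last.
build_gene_structures <- function(genes) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) {
    return(list(exons = empty, utr5 = empty, utr3 = empty))
  }
  exon_list <- vector("list", nrow(genes))
  utr5_list <- vector("list", nrow(genes))
  utr3_list <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    n_ex <- sample(1:3, 1L)
    n_seg <- 2L * n_ex - 1L                      # exon/intron alternation
    # segment widths: minimum 60 bp each, remainder split at random
    min_w <- 60L
    spare <- len - n_seg * min_w
    if (spare < 0L) { n_ex <- 1L; n_seg <- 1L; spare <- len - min_w }
    w <- min_w + floor(diff(c(0, sort(runif(n_seg - 1L)), 1)) * spare)
    w[n_seg] <- len - sum(w[-n_seg])
    bounds <- g$start + cumsum(c(0L, w))
    seg_start <- bounds[seq_len(n_seg)]
    seg_end <- bounds[seq_len(n_seg) + 1L]
    is_exon <- seq_len(n_seg) %% 2L == 1L
    ex <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                     start = as.integer(seg_start[is_exon]),
                     end = as.integer(seg_end[is_exon]),
                     stringsAsFactors = FALSE)
    exon_list[[i]] <- ex
    first_ex <- ex[1L, ]; last_ex <- ex[nrow(ex), ]
    # UTR widths bounded by the exon each UTR is carved from
    lead_ex <- if (g$strand == "+") first_ex else last_ex   # 5' end
    tail_ex <- if (g$strand == "+") last_ex else first_ex   # 3' end
    u5_w <- max(20L, min(150L, (lead_ex$end - lead_ex$start) %/% 4L))
    u3_w <- max(20L, min(300L, (tail_ex$end - tail_ex$start) %/% 3L))
    if (g$strand == "+") {
      utr5_list[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                   start = first_ex$start,
                                   end = first_ex$start + u5_w,
                                   stringsAsFactors = FALSE)
      utr3_list[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                   start = last_ex$end - u3_w,
                                   end = last_ex$end,
                                   stringsAsFactors = FALSE)
    } else {
      utr5_list[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                   start = last_ex$end - u5_w,
                                   end = last_ex$end,
                                   stringsAsFactors = FALSE)
      utr3_list[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                   start = first_ex$start,
                                   end = first_ex$start + u3_w,
                                   stringsAsFactors = FALSE)
    }
  }
  list(exons = do.call(rbind, exon_list),
       utr5 = do.call(rbind, utr5_list),
       utr3 = do.call(rbind, utr3_list))
}

# Interval track covering ~ target_fraction of each chromosome, again by
# random gap allocation so intervals never overlap.
place_track <- function(chrom_lengths, target_fraction, len_range) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    mean_len <- mean(len_range)
    k <- floor(target_fraction * L / mean_len)
    if (k < 1L) next
    lens <- sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
    while (sum(lens) > 0.95 * L) lens <- lens[-length(lens)]
    k <- length(lens)
    if (k == 0L) next
    free <- L - sum(lens)
    cuts <- sort(runif(k))
    gaps <- floor(diff(c(0, cuts, 1)) * free)
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
    out[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                            end = as.integer(starts + lens),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d chromosome(s), %d genes, %d repeat intervals, %d accessible intervals\n",
    length(x$chrom_lengths), nrow(x$genes), nrow(x$repeats),
    nrow(x$accessible)))
  invisible(x)
}
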