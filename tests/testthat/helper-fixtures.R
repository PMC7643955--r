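# Shared fixtures: a scaled-down simulation config for fast tests and a
# hand-built annotation with known coordinates for the feature-classification
# oracles.

small_cfg <- function(...) {
  args <- list(n_chroms = 1L, chrom_length = 100000L, n_genes = 12L,
               n_planted_dmrs = 4L, n_planted_degs = 6L,
               n_spikein_sites = 300L, coverage_rate = 2, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# annotation with two genes on a 100 kb chromosome:
#   g1: + strand, span [10000, 20000), TSS 10000,
#       exons [10000,12000) and [15000,20000),
#       5'UTR [10000,11000) (its tail lies beyond the promoter end 10500),
#       3'UTR [19000,20000)
#   g2: - strand, span [50000, 60000), TSS 59999,
#       exons [50000,54000) and [57000,60000),
#       5'UTR [59500,60000), 3'UTR [50000,50400)
manual_annotation <- function(repeats = NULL, accessible = NULL) {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000L, 50000L), end = c(20000L, 60000L),
    tss = c(10000L, 59999L), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2"), chrom = "chr1",
    start = c(10000L, 15000L, 50000L, 57000L),
    end = c(12000L, 20000L, 54000L, 60000L), stringsAsFactors = FALSE)
  utr5 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     start = c(10000L, 59500L), end = c(11000L, 60000L),
                     stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     start = c(19000L, 50000L), end = c(20000L, 50400L),
                     stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  structure(list(
    genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
    repeats = if (is.null(repeats)) cbind(empty,
      data.frame(family = character())) else repeats,
    accessible = accessible %||% empty,
    chrom_lengths = c(chr1 = 100000L), genome = NULL
  ), class = "genome_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_regions <- function(n, chrom_lengths, width_range = c(50L, 4000L)) {
  ch <- sample(names(chrom_lengths), n, replace = TRUE)
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  st <- vapply(seq_len(n), function(i) {
    sample.int(chrom_lengths[[ch[i]]] - w[i], 1L) - 1L
  }, integer(1))
  data.frame(chrom = ch, start = st, end = st + w, stringsAsFactors = FALSE)
}

# per-base overlap oracle: does region i share any base with the track?
per_base_overlap <- function(regions, track) {
  vapply(seq_len(nrow(regions)), function(i) {
    r_bases <- seq.int(regions$start[i], regions$end[i] - 1L)
    any(vapply(seq_len(nrow(track)), function(j) {
      track$chrom[j] == regions$chrom[i] &&
        any(r_bases >= track$start[j] & r_bases < track$end[j])
    }, logical(1)))
  }, logical(1))
}

# small cytosine-call table builder
make_calls <- function(chrom, pos, meth, total, context = "CHH",
                       strand = "+", cell_id = "c1", stage = "A") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         meth_count = as.integer(meth),
                         total_count = as.integer(total),
                         cell_id = cell_id, stage = stage)
}
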