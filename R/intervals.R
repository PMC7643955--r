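# Interval conventions: everything internal is 0-based, half-open [start, end).
# GRanges (1-based, closed) is used as the overlap engine; the two helpers
# below are the only place the conversion happens.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `strand`.
#' @return a [GenomicRanges::GRanges] object (1-based, closed).
#' @keywords internal
as_granges0 <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  str <- if ("strand" %in% names(df)) df$strand else "*"
  str[!str %in% c("+", "-", "*")] <- "*"   # e.g. BED "." placeholder
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = str
  )
}

#' Convert a GRanges back to a 0-based half-open data.frame
#' @keywords internal
granges_to_df0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping genomic intervals
#'
#' Collapses a set of intervals into the minimal set of maximal intervals
#' covering the same bases. Abutting half-open intervals (e.g. `[0,10)` and
#' `[10,20)`) share no base and are *not* merged.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return data.frame of merged intervals, sorted by chromosome and start.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(intervals$end > intervals$start))
  gr <- as_granges0(intervals[, c("chrom", "start", "end")])
  # min.gapwidth = 0L: merge only true overlaps, never adjacency
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  out <- granges_to_df0(merged)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Does each region overlap any interval of a track?
#' @keywords internal
overlaps_any0 <- function(regions, track) {
  if (nrow(regions) == 0L) return(logical(0))
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, nrow(regions)))
  IRanges::overlapsAny(as_granges0(regions), as_granges0(track),
                       ignore.strand = TRUE)
}
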