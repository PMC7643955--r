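#' Strand-aware promoter intervals
#'
#' Promoters span 2000 bp upstream to 500 bp downstream of the TSS. With
#' 0-based half-open coordinates a + strand gene with TSS t yields
#' `[t - 2000, t + 500)` and a - strand gene `[t - 499, t + 2001)`; intervals
#' are clipped to chromosome bounds.
#'
#' @param annotation a `genome_annotation`.
#' @param upstream,downstream extent in bp (defaults 2000 / 500).
#' @return data.frame with gene_id, chrom, start, end.
#' @export
promoter_intervals <- function(annotation, upstream = 2000L,
                               downstream = 500L) {
  g <- annotation$genes
  if (nrow(g) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream + 1L)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream + 1L)
  lens <- annotation$chrom_lengths[g$chrom]
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = as.integer(pmax(0L, start)),
             end = as.integer(pmin(lens, end)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Tier tracks used by classify_feature / is_distal.
feature_tracks <- function(annotation, promoters = NULL) {
  list(
    promoter = promoters %||% promoter_intervals(annotation),
    utr5 = annotation$utr5,
    utr3 = annotation$utr3,
    exon = annotation$exons,
    gene = annotation$genes
  )
}

#' Is a region distal?
#'
#' A region is distal when it overlaps no promoter (-2 kb/+500 bp of any
#' TSS), no exon, and no UTR of any gene. Introns and intergenic space both
#' qualify — the definition is taken literally and does not exclude introns.
#'
#' @param region a single region (list/row with chrom, start, end) or a
#'   data.frame of regions.
#' @param annotation a `genome_annotation`.
#' @return logical vector, one verdict per region.
#' @export
is_distal <- function(region, annotation) {
  regions <- as.data.frame(region, stringsAsFactors = FALSE)
  tr <- feature_tracks(annotation)
  !(overlaps_any0(regions, tr$promoter) |
      overlaps_any0(regions, tr$exon) |
      overlaps_any0(regions, tr$utr5) |
      overlaps_any0(regions, tr$utr3))
}

#' Classify regions against genic features
#'
#' Assigns exactly one label per region under the priority
#' promoter > 5'UTR > 3'UTR > exon > intron > distal, each tier decided by
#' any-overlap. "intron" means the region overlaps a gene span but none of
#' the higher tiers; everything else is "distal".
#'
#' @param region a single region or a data.frame of regions (chrom, start,
#'   end; 0-based half-open).
#' @param annotation a `genome_annotation`.
#' @return character vector of labels.
#' @export
classify_feature <- function(region, annotation) {
  regions <- as.data.frame(region, stringsAsFactors = FALSE)
  tr <- feature_tracks(annotation)
  lab <- rep("distal", nrow(regions))
  in_gene <- overlaps_any0(regions, tr$gene)
  lab[in_gene] <- "intron"
  lab[overlaps_any0(regions, tr$exon)] <- "exon"
  lab[overlaps_any0(regions, tr$utr3)] <- "3'UTR"
  lab[overlaps_any0(regions, tr$utr5)] <- "5'UTR"
  lab[overlaps_any0(regions, tr$promoter)] <- "promoter"
  lab
}

#' Fraction of regions overlapping a track
#'
#' The fraction of query regions having at least 1 bp of overlap with any
#' track interval (e.g. distal DMRs vs DNase accessibility, DMRs vs
#' transposable elements). Invariant to merging of the track.
#'
#' @param regions data.frame of regions (chrom, start, end).
#' @param track data.frame of track intervals.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(regions, track) {
  if (nrow(regions) == 0L) {
    stop("overlap_fraction is undefined for an empty region set")
  }
  mean(overlaps_any0(regions, track))
}

#' Nearest gene by TSS distance
#'
#' Returns, per region, the gene whose TSS is closest to the region midpoint
#' and within `max_dist` bp; ties broken by the lexicographically lower gene
#' id. A transparent stand-in for regulatory-domain assignment of distal
#' regions to genes.
#'
#' @param region a single region or data.frame of regions.
#' @param annotation a `genome_annotation`.
#' @param max_dist maximum midpoint-to-TSS distance in bp (default 1e5).
#' @return data.frame with gene_id (NA when no gene qualifies) and distance.
#' @export
nearest_gene <- function(region, annotation, max_dist = 100000L) {
  regions <- as.data.frame(region, stringsAsFactors = FALSE)
  g <- annotation$genes
  out <- data.frame(gene_id = rep(NA_character_, nrow(regions)),
                    distance = rep(NA_real_, nrow(regions)),
                    stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(out)
  ord <- order(g$gene_id)
  g <- g[ord, , drop = FALSE]
  mid <- floor((regions$start + regions$end) / 2)
  for (i in seq_len(nrow(regions))) {
    same <- g$chrom == regions$chrom[i]
    if (!any(same)) next
    d <- abs(g$tss[same] - mid[i])
    j <- which.min(d)            # first minimum = lowest gene id after sort
    if (d[j] <= max_dist) {
      out$gene_id[i] <- g$gene_id[same][j]
      out$distance[i] <- d[j]
    }
  }
  out
}

#' Summarise DMR genomic context
#'
#' Convenience wrapper used by the analysis drivers: classifies each DMR,
#' flags distal ones, and computes per-(context, direction) fractions of
#' distal DMRs plus track-overlap fractions.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param annotation a `genome_annotation`.
#' @return list with `dmrs` (input plus feature/distal columns) and
#'   `summary` (per context x direction: n, frac_distal, frac_in_repeats,
#'   frac_distal_accessible).
#' @export
classify_dmrs <- function(dmrs, annotation) {
  if (nrow(dmrs) == 0L) {
    return(list(dmrs = dmrs, summary = data.frame()))
  }
  dmrs$feature <- classify_feature(dmrs, annotation)
  dmrs$distal <- is_distal(dmrs, annotation)
  dmrs$in_repeat <- overlaps_any0(dmrs, annotation$repeats)
  dmrs$accessible <- overlaps_any0(dmrs, annotation$accessible)
  summ <- do.call(rbind, lapply(
    split(dmrs, list(dmrs$context, dmrs$direction), drop = TRUE),
    function(d) data.frame(
      context = d$context[1], direction = d$direction[1], n = nrow(d),
      frac_distal = mean(d$distal), frac_in_repeats = mean(d$in_repeat),
      frac_distal_accessible = if (any(d$distal))
        mean(d$accessible[d$distal]) else NA_real_,
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(dmrs = dmrs, summary = summ)
}
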