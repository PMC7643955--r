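#' Bisulfite conversion efficiency from lambda spike-ins
#'
#' Lambda phage DNA is unmethylated, so any methylated call on the spike-in
#' is a conversion failure: efficiency = 1 - sum(meth) / sum(total).
#'
#' @param spikein_calls data.frame/data.table of cytosine calls with
#'   `meth_count` and `total_count` columns.
#' @return efficiency, a fraction in `[0, 1]`.
#' @export
conversion_efficiency <- function(spikein_calls) {
  tot <- sum(as.numeric(spikein_calls$total_count))
  if (!is.finite(tot) || tot <= 0) {
    stop("conversion efficiency is undefined: zero total spike-in coverage")
  }
  1 - sum(as.numeric(spikein_calls$meth_count)) / tot
}

#' Per-library conversion QC
#'
#' Computes efficiency per cell and flags libraries at or below the
#' threshold (libraries in the study all exceeded 98%).
#'
#' @param spikein_calls spike-in call table with a `cell_id` column.
#' @param threshold minimum acceptable efficiency (default 0.98).
#' @return data.frame with cell_id, efficiency, pass.
#' @export
conversion_qc <- function(spikein_calls, threshold = 0.98) {
  dt <- data.table::as.data.table(spikein_calls)
  res <- dt[, .(efficiency = 1 - sum(as.numeric(meth_count)) /
                  sum(as.numeric(total_count))), by = cell_id]
  res[, `:=`(pass = efficiency > threshold)]
  as.data.frame(res)
}

#' Coverage-weighted methylation level of a region
#'
#' Level = sum(meth) / sum(total) over in-region, in-context sites — the
#' coverage-weighted mean, computed per context separately. When no covered
#' site falls in the region the level is `NA` (an explicit "no data" result,
#' never 0).
#'
#' @param calls cytosine call table (chrom, pos, context, meth_count,
#'   total_count, ...).
#' @param region optional list/data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open); `NULL` uses all calls.
#' @param context optional context label ("CpG", "CHG", "CHH"); `NULL` pools
#'   all contexts.
#' @return list with `level` (fraction or NA) and `coverage` (summed total
#'   counts).
#' @export
methylation_level <- function(calls, region = NULL, context = NULL) {
  dt <- data.table::as.data.table(calls)
  if (!is.null(context)) {
    ctx <- context_label(context)
    dt <- dt[which(dt$context == ctx)]
  }
  if (!is.null(region)) {
    dt <- dt[which(dt$chrom == region$chrom & dt$pos >= region$start &
                     dt$pos < region$end)]
  }
  cov <- sum(as.numeric(dt$total_count))
  if (cov == 0) return(list(level = NA_real_, coverage = 0))
  list(level = sum(as.numeric(dt$meth_count)) / cov, coverage = cov)
}

context_label <- function(x) {
  m <- c(cpg = "CpG", chg = "CHG", chh = "CHH")
  if (tolower(x) %in% names(m)) unname(m[tolower(x)]) else x
}

#' Pool cytosine calls across cells
#'
#' Sums methylated and total counts per site within each group (stage by
#' default), producing the pooled profile the window tests run on. Pooled
#' counts at a site are exactly the sum of the member cells' counts.
#'
#' @param calls call table with a grouping column.
#' @param by grouping column name (default "stage").
#' @return data.table with chrom, pos, strand, context, group, meth, total.
#' @export
pool_cells <- function(calls, by = "stage") {
  dt <- data.table::as.data.table(calls)
  out <- dt[, .(meth = sum(as.numeric(meth_count)),
                total = sum(as.numeric(total_count))),
            by = c("chrom", "pos", "strand", "context", by)]
  data.table::setnames(out, by, "group")
  data.table::setorder(out, group, chrom, pos, strand)
  out[]
}

#' Genome-wide sliding windows
#'
#' Per chromosome, windows of `width` bp start at 0, step, 2*step, ...
#' For a chromosome of length L >= width there are
#' floor((L - width)/step) + 1 regular windows; when the last regular window
#' ends before L one terminal window `[L - width, L)` is appended so the
#' whole genome is covered. Chromosomes shorter than `width` get the single
#' truncated window `[0, L)`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width window width in bp (default 3000).
#' @param step step size in bp (default 600).
#' @return data.table with chrom, start, end, ordered by chrom then start.
#' @export
sliding_windows <- function(chrom_lengths, width = 3000L, step = 600L) {
  stopifnot(width >= step, step > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    if (L < width) {
      return(data.table::data.table(chrom = ch, start = 0L, end = L))
    }
    starts <- seq.int(0L, L - width, by = step)
    ends <- starts + width
    if (ends[length(ends)] < L) {
      starts <- c(starts, L - width)
      ends <- c(ends, L)
    }
    data.table::data.table(chrom = ch, start = as.integer(starts),
                           end = as.integer(ends))
  })
  data.table::rbindlist(out)[]
}

# Two-sided Fisher exact p-value on 2x2 tables via the doubling rule:
# p = min(1, 2 * min(lower tail, upper tail)) of the hypergeometric for the
# observed methylated count in group A. Vectorised over tables.
fisher_doubling <- function(mA, uA, mB, uB) {
  K <- mA + mB              # methylated calls overall
  n <- mA + uA              # draws = group A total
  N <- mA + uA + mB + uB
  p_low <- phyper(mA, K, N - K, n)
  p_high <- phyper(mA - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, 2 * pmin(p_low, p_high))
}

#' Test one window for differential methylation
#'
#' Pools the counts of each group's profile inside the window and applies a
#' two-sided Fisher exact test (doubling rule) to the 2x2 table of
#' (methylated, unmethylated) counts. A window where either group has pooled
#' coverage below `min_cov` is untestable and is excluded from the
#' multiple-testing universe.
#'
#' @param poolA,poolB pooled profiles ([pool_cells()]) of the same context;
#'   A is the earlier stage, B the later.
#' @param window list/row with chrom, start, end.
#' @param context context label to restrict to (required when the pools
#'   carry several contexts).
#' @param min_cov minimum pooled coverage per group (default 10).
#' @return list with delta (level_B - level_A), p, cov_A, cov_B, testable.
#' @export
test_window <- function(poolA, poolB, window, context = NULL, min_cov = 10) {
  ctx <- if (is.null(context)) NULL else context_label(context)
  pick <- function(pool) {
    dt <- data.table::as.data.table(pool)
    if (!is.null(ctx)) dt <- dt[which(dt$context == ctx)]
    dt <- dt[which(dt$chrom == window$chrom & dt$pos >= window$start &
                     dt$pos < window$end)]
    c(meth = sum(dt$meth), total = sum(dt$total))
  }
  a <- pick(poolA); b <- pick(poolB)
  testable <- a["total"] >= min_cov && b["total"] >= min_cov
  if (!testable) {
    return(list(delta = NA_real_, p = NA_real_, cov_A = unname(a["total"]),
                cov_B = unname(b["total"]), testable = FALSE))
  }
  delta <- b["meth"] / b["total"] - a["meth"] / a["total"]
  p <- fisher_doubling(a["meth"], a["total"] - a["meth"],
                       b["meth"], b["total"] - b["meth"])
  list(delta = unname(delta), p = unname(p), cov_A = unname(a["total"]),
       cov_B = unname(b["total"]), testable = TRUE)
}

#' Call differentially methylated regions for one context
#'
#' Pipeline: pool cells per group, tile the genome with sliding windows,
#' Fisher-test every testable window, Benjamini-Hochberg across testable
#' windows, keep windows with q <= q_max and |delta| >= delta_min, and merge
#' overlapping significant windows of the same direction into DMRs (per
#' context). Direction is labelled relative to group B (the later stage):
#' "hyper" means higher methylation in B.
#'
#' @param cells_a,cells_b cytosine call tables (>= 1 cell each); A is the
#'   earlier maturation stage.
#' @param context context to call ("CpG", "CHG" or "CHH").
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width,step sliding-window geometry (default 3000/600).
#' @param q_max BH q-value threshold (default 0.05).
#' @param delta_min minimum |level_B - level_A| (default 0.1).
#' @param min_cov minimum pooled coverage per group per window (default 10).
#' @return data.frame of DMRs: chrom, start, end, context, direction,
#'   level_A, level_B, delta, q, n_windows_merged; sorted and non-overlapping
#'   within (context, direction). Empty (with a message) when no window is
#'   testable.
#' @export
call_dmrs <- function(cells_a, cells_b, context, chrom_lengths,
                      width = 3000L, step = 600L, q_max = 0.05,
                      delta_min = 0.1, min_cov = 10) {
  ctx <- context_label(context)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), level_A = numeric(),
                      level_B = numeric(), delta = numeric(), q = numeric(),
                      n_windows_merged = integer(), stringsAsFactors = FALSE)

  poolA <- pool_context(cells_a, ctx)
  poolB <- pool_context(cells_b, ctx)
  tab <- dmr_window_table(cells_a, cells_b, ctx, chrom_lengths, width, step,
                          min_cov, pools = list(A = poolA, B = poolB))
  if (!any(tab$testable)) {
    message("call_dmrs: no testable window for context ", ctx,
            " (pooled coverage below ", min_cov, " everywhere)")
    return(empty)
  }
  tst <- data.table::as.data.table(tab[tab$testable, , drop = FALSE])
  sig <- tst[q <= q_max & abs(delta) >= delta_min]
  if (nrow(sig) == 0L) return(empty)
  sig[, `:=`(direction = ifelse(delta > 0, "hyper", "hypo"))]

  out <- list()
  for (dir in unique(sig$direction)) {
    sd_ <- sig[direction == dir]
    merged <- merge_intervals(as.data.frame(sd_[, .(chrom, start, end)]))
    hits <- GenomicRanges::findOverlaps(as_granges0(merged),
                                        as_granges0(as.data.frame(sd_)),
                                        ignore.strand = TRUE)
    qmin <- tapply(sd_$q[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), min)
    nwin <- tapply(S4Vectors::subjectHits(hits),
                   S4Vectors::queryHits(hits), length)
    merged$context <- ctx
    merged$direction <- dir
    lv <- region_levels(merged, poolA, poolB)
    merged$level_A <- lv$level_A
    merged$level_B <- lv$level_B
    merged$delta <- merged$level_B - merged$level_A
    merged$q <- as.numeric(qmin[as.character(seq_len(nrow(merged)))])
    merged$n_windows_merged <-
      as.integer(nwin[as.character(seq_len(nrow(merged)))])
    out[[dir]] <- merged
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "context", "direction", "level_A",
          "level_B", "delta", "q", "n_windows_merged")]
}

#' Per-window differential-methylation test table
#'
#' The window-level statistics [call_dmrs()] is built on: pooled counts per
#' group per sliding window, testability (both groups at or above `min_cov`),
#' delta = level_B - level_A, the two-sided Fisher (doubling rule) p-value,
#' and the BH q-value computed across testable windows only.
#'
#' @inheritParams call_dmrs
#' @param pools internal: precomputed pooled profiles.
#' @return data.frame, one row per window: chrom, start, end, meth_A,
#'   total_A, meth_B, total_B, testable, delta, p, q (NA where untestable).
#' @export
dmr_window_table <- function(cells_a, cells_b, context, chrom_lengths,
                             width = 3000L, step = 600L, min_cov = 10,
                             pools = NULL) {
  ctx <- context_label(context)
  if (is.null(pools)) {
    pools <- list(A = pool_context(cells_a, ctx),
                  B = pool_context(cells_b, ctx))
  }
  windows <- sliding_windows(chrom_lengths, width, step)
  wA <- window_counts(windows, pools$A)
  wB <- window_counts(windows, pools$B)
  out <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    mA = wA$meth, tA = wA$total, mB = wB$meth, tB = wB$total,
    stringsAsFactors = FALSE)
  out$testable <- out$tA >= min_cov & out$tB >= min_cov
  out$delta <- NA_real_; out$p <- NA_real_; out$q <- NA_real_
  i <- out$testable
  if (any(i)) {
    out$delta[i] <- out$mB[i] / out$tB[i] - out$mA[i] / out$tA[i]
    out$p[i] <- fisher_doubling(out$mA[i], out$tA[i] - out$mA[i],
                                out$mB[i], out$tB[i] - out$mB[i])
    out$q[i] <- p.adjust(out$p[i], method = "BH")
  }
  names(out)[names(out) %in% c("mA", "tA", "mB", "tB")] <-
    c("meth_A", "total_A", "meth_B", "total_B")
  out
}

# Pool all cells of one call table for one context (site-level sums).
pool_context <- function(calls, ctx) {
  dt <- data.table::as.data.table(calls)
  dt <- dt[dt$context == ctx]
  out <- dt[, .(meth = sum(as.numeric(meth_count)),
                total = sum(as.numeric(total_count))),
            by = .(chrom, pos, strand)]
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

# Aggregate pooled site counts into windows (sites can fall in several
# overlapping windows).
window_counts <- function(windows, pool) {
  n <- nrow(windows)
  res <- data.frame(meth = numeric(n), total = numeric(n))
  if (nrow(pool) == 0L) return(res)
  wgr <- as_granges0(as.data.frame(windows))
  sgr <- GenomicRanges::GRanges(pool$chrom,
                                IRanges::IRanges(pool$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(wgr, sgr)
  if (length(hits) == 0L) return(res)
  agg <- data.table::data.table(
    w = S4Vectors::queryHits(hits),
    meth = pool$meth[S4Vectors::subjectHits(hits)],
    total = pool$total[S4Vectors::subjectHits(hits)])
  agg <- agg[, .(meth = sum(meth), total = sum(total)), by = w]
  res$meth[agg$w] <- agg$meth
  res$total[agg$w] <- agg$total
  res
}

# Weighted methylation levels of arbitrary regions from two pooled profiles.
region_levels <- function(regions, poolA, poolB) {
  lev <- function(pool) {
    vapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      sel <- pool$chrom == r$chrom & pool$pos >= r$start & pool$pos < r$end
      tot <- sum(pool$total[sel])
      if (tot == 0) NA_real_ else sum(pool$meth[sel]) / tot
    }, numeric(1))
  }
  list(level_A = lev(poolA), level_B = lev(poolB))
}
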