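#' Enumerate cytosines of a genome with Bismark-style contexts
#'
#' Both strands are enumerated independently (never collapsed): a plus-strand
#' cytosine at position i is CpG when base i+1 is G, CHG when base i+2 is G,
#' CHH otherwise; minus-strand sites are the Gs of the plus strand with the
#' mirrored rule. Sites within 2 bp of a chromosome end, where the context is
#' undefined, are dropped.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @return data.table with columns chrom, pos (0-based), strand, context.
#' @export
enumerate_cytosines <- function(genome) {
  res <- vector("list", 2L * length(genome))
  k <- 0L
  for (ch in names(genome)) {
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    L <- length(s)
    # plus strand
    i <- which(s == "C")
    i <- i[i <= L - 2L]
    if (length(i)) {
      ctx <- ifelse(s[i + 1L] == "G", "CpG",
                    ifelse(s[i + 2L] == "G", "CHG", "CHH"))
      k <- k + 1L
      res[[k]] <- data.table::data.table(chrom = ch, pos = i - 1L,
                                         strand = "+", context = ctx)
    }
    # minus strand (G on plus strand)
    j <- which(s == "G")
    j <- j[j >= 3L]
    if (length(j)) {
      ctx <- ifelse(s[j - 1L] == "C", "CpG",
                    ifelse(s[j - 2L] == "C", "CHG", "CHH"))
      k <- k + 1L
      res[[k]] <- data.table::data.table(chrom = ch, pos = j - 1L,
                                         strand = "-", context = ctx)
    }
  }
  if (k == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character()))
  }
  out <- data.table::rbindlist(res[seq_len(k)])
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Simulate per-cell methylomes with planted non-CpG DMRs
#'
#' Draws, for every cytosine and cell, coverage ~ Poisson(coverage_rate) and
#' methylated counts ~ Binomial(coverage, site mean). CpG site means equal
#' `cpg_mean` in every stage; CHG/CHH means are `noncpg_mean_immature` in GV
#' and MI and `noncpg_mean_mature` in MII (the genome-wide doubling of
#' non-CpG methylation in mature oocytes). Inside each planted DMR the MII
#' mean of the DMR's context is raised by `dmr_effect`. A lambda spike-in
#' table with the configured conversion-failure rate is generated alongside.
#'
#' @param annotation a [simulate_annotation()] result.
#' @param config a [sim_config()] object.
#' @return list with `calls` (data.table: chrom, pos, strand, context,
#'   meth_count, total_count, cell_id, stage), `spikein` (same layout,
#'   chrom "lambda"), `truth` (a `truth_set`), and `annotation` (updated
#'   when a TF motif was embedded into planted DMRs).
#' @export
simulate_methylome <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)

  planted <- place_planted_dmrs(annotation, config)
  if (!is.null(config$tf_motif) && nrow(planted) > 0L) {
    emb <- embed_motif(annotation, planted, config)
    annotation <- emb$annotation
    motifs <- emb$motifs
  } else {
    motifs <- data.frame(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         motif = character(), stringsAsFactors = FALSE)
  }

  sites <- enumerate_cytosines(annotation$genome)
  mii_mean <- site_means(sites, planted, config, mature = TRUE)
  imm_mean <- site_means(sites, planted, config, mature = FALSE)

  n_stage <- length(config$stages)
  mature_stage <- config$stages[n_stage]
  calls <- vector("list", n_stage * config$n_cells_per_stage)
  k <- 0L
  for (st in config$stages) {
    mu <- if (st == mature_stage) mii_mean else imm_mean
    for (ci in seq_len(config$n_cells_per_stage)) {
      k <- k + 1L
      cov <- rpois(nrow(sites), config$coverage_rate)
      keep <- cov > 0L
      m <- mu[keep]
      if (config$cell_meth_sd > 0) {
        m <- plogis(qlogis(pmin(pmax(m, 1e-6), 1 - 1e-6)) +
                      rnorm(1L, 0, config$cell_meth_sd))
      }
      meth <- rbinom(sum(keep), cov[keep], m)
      tab <- sites[keep]
      tab[, `:=`(meth_count = meth, total_count = cov[keep],
                 cell_id = sprintf("%s_%d", st, ci), stage = st)]
      calls[[k]] <- tab
    }
  }
  calls <- data.table::rbindlist(calls)

  spikein <- simulate_spikein(config)
  truth <- structure(list(
    planted_dmrs = planted,
    planted_motifs = motifs,
    planted_degs = data.frame(gene_id = character(), log2fc = numeric(),
                              stringsAsFactors = FALSE),
    dmr_deg_links = data.frame(gene_id = character(), dmr_id = character(),
                               stringsAsFactors = FALSE)
  ), class = "truth_set")

  list(calls = calls, spikein = spikein, truth = truth,
       annotation = annotation)
}

# Planted DMRs: `frac_dmr_in_repeats` of them inside repeat intervals wide
# enough to contain them, the rest clear of repeats; all pairwise separated
# by > window+step so each is recovered as its own merged region.
place_planted_dmrs <- function(annotation, config) {
  n <- config$n_planted_dmrs
  empty <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      context = character(), direction = character(),
                      effect = numeric(), in_repeat = logical(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  w <- config$dmr_width
  min_sep <- w + 1200L
  n_rep <- round(config$frac_dmr_in_repeats * n)
  reps <- annotation$repeats
  big <- reps[reps$end - reps$start >= w, , drop = FALSE]
  placed <- list()
  too_close <- function(cand) {
    if (length(placed) == 0L) return(FALSE)
    cur <- do.call(rbind, placed)
    any(cur$chrom == cand$chrom &
          cand$start < cur$end + min_sep & cur$start < cand$end + min_sep)
  }
  # inside repeats
  if (n_rep > 0L) {
    if (nrow(big) < n_rep) {
      stop(sprintf(
        "cannot place %d DMRs inside repeats: only %d repeat intervals are >= %d bp",
        n_rep, nrow(big), w))
    }
    ord <- sample(nrow(big))
    for (ri in ord) {
      if (length(placed) >= n_rep) break
      r <- big[ri, ]
      off <- if (r$end - r$start == w) 0L else
        sample.int(r$end - r$start - w, 1L) - 1L
      cand <- data.frame(chrom = r$chrom, start = r$start + off,
                         end = r$start + off + w, in_repeat = TRUE,
                         stringsAsFactors = FALSE)
      if (!too_close(cand)) placed[[length(placed) + 1L]] <- cand
    }
    if (length(placed) < n_rep) {
      stop("could not place the requested number of repeat-resident DMRs ",
           "with the required separation; lower n_planted_dmrs or ",
           "frac_dmr_in_repeats")
    }
  }
  # outside repeats, rejection sampling
  n_out <- n - length(placed)
  attempts <- 0L
  while (n_out > 0L && attempts < 20000L) {
    attempts <- attempts + 1L
    ch <- sample(names(annotation$chrom_lengths), 1L)
    st <- sample.int(annotation$chrom_lengths[[ch]] - w, 1L) - 1L
    cand <- data.frame(chrom = ch, start = st, end = st + w,
                       in_repeat = FALSE, stringsAsFactors = FALSE)
    in_rep <- overlaps_any0(cand, reps)
    if (!in_rep && !too_close(cand)) {
      placed[[length(placed) + 1L]] <- cand
      n_out <- n_out - 1L
    }
  }
  if (n_out > 0L) {
    stop("could not place all repeat-free DMRs; genome too crowded")
  }
  out <- do.call(rbind, placed)
  out$dmr_id <- sprintf("planted%03d", seq_len(nrow(out)))
  out$context <- sample(c("CHH", "CHG"), nrow(out), replace = TRUE,
                        prob = c(0.7, 0.3))
  out$direction <- "hyper"
  out$effect <- config$dmr_effect
  rownames(out) <- NULL
  out[, c("dmr_id", "chrom", "start", "end", "context", "direction",
          "effect", "in_repeat")]
}

# Write the consensus motif into the genome inside a fraction of planted
# DMRs (done before cytosine enumeration so contexts stay consistent).
embed_motif <- function(annotation, planted, config) {
  consensus <- config$tf_motif
  mlen <- nchar(consensus)
  n_emb <- round(config$tf_motif_frac * nrow(planted))
  idx <- sort(sample.int(nrow(planted), n_emb))
  recs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    d <- planted[idx[i], ]
    off <- sample.int(d$end - d$start - mlen, 1L) - 1L
    pos <- d$start + off            # 0-based
    Biostrings::subseq(annotation$genome[[d$chrom]],
                       start = pos + 1L, width = mlen) <-
      Biostrings::DNAString(consensus)
    recs[[i]] <- data.frame(chrom = d$chrom, start = pos, end = pos + mlen,
                            strand = "+", motif = consensus,
                            dmr_id = d$dmr_id, stringsAsFactors = FALSE)
  }
  list(annotation = annotation, motifs = do.call(rbind, recs))
}

# Per-site binomial means for one stage class (mature vs immature).
site_means <- function(sites, planted, config, mature) {
  mu <- ifelse(sites$context == "CpG", config$cpg_mean,
               if (mature) config$noncpg_mean_mature else
                 config$noncpg_mean_immature)
  if (mature && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      d <- planted[i, ]
      hit <- sites$chrom == d$chrom & sites$pos >= d$start &
        sites$pos < d$end & sites$context == d$context
      mu[hit] <- mu[hit] + d$effect
    }
    if (any(mu > 1)) {
      warning("dmr_effect pushes some site means above 1; clamped to 1")
      mu <- pmin(mu, 1)
    }
  }
  mu
}

# Unmethylated lambda spike-in: any methylated call is a conversion failure.
simulate_spikein <- function(config) {
  n <- config$n_spikein_sites
  cells <- as.vector(outer(seq_len(config$n_cells_per_stage), config$stages,
                           function(i, st) sprintf("%s_%d", st, i)))
  stages <- rep(config$stages, each = config$n_cells_per_stage)
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cov <- rpois(n, config$spikein_coverage)
    keep <- cov > 0L
    meth <- rbinom(sum(keep), cov[keep], config$conversion_failure_rate)
    out[[k]] <- data.table::data.table(
      chrom = "lambda", pos = which(keep) - 1L, strand = "+",
      context = "CpG", meth_count = meth, total_count = cov[keep],
      cell_id = cells[k], stage = stages[k])
  }
  data.table::rbindlist(out)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %d planted DMRs, %d planted DEGs, %d DMR-DEG links, %d embedded motifs\n",
    nrow(x$planted_dmrs), nrow(x$planted_degs), nrow(x$dmr_deg_links),
    nrow(x$planted_motifs)))
  invisible(x)
}
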