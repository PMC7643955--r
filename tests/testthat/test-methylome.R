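test_that("conversion efficiency follows its definition and QC gate", {
  all_conv <- make_calls("lambda", 0:9, meth = 0, total = 10)
  expect_identical(conversion_efficiency(all_conv), 1)
  some <- make_calls("lambda", 0:9, meth = c(2, rep(0, 9)),
                     total = c(10, rep(10, 9)))
  expect_equal(conversion_efficiency(some), 0.98)
  none <- make_calls("lambda", 0:2, meth = 0, total = 0)
  expect_error(conversion_efficiency(none), "undefined")
  # libraries at or below 98% are flagged
  bad <- make_calls("lambda", 0:99, meth = 2, total = 100, cell_id = "bad")
  ok <- make_calls("lambda", 0:99, meth = 1, total = 100, cell_id = "ok")
  qc <- conversion_qc(rbind(bad, ok))
  expect_identical(qc$pass[qc$cell_id == "bad"], FALSE)  # exactly 0.98
  expect_identical(qc$pass[qc$cell_id == "ok"], TRUE)
})

test_that("methylation level is the coverage-weighted mean", {
  calls <- make_calls("chr1", c(100, 200), meth = c(5, 3), total = c(10, 10))
  r <- methylation_level(calls, list(chrom = "chr1", start = 0, end = 300))
  expect_equal(r$level, 0.4)
  expect_equal(r$coverage, 20)
  # empty region is "no data", not zero
  r0 <- methylation_level(calls, list(chrom = "chr1", start = 500, end = 600))
  expect_true(is.na(r0$level))
  expect_identical(r0$coverage, 0)
})

test_that("methylation level matches site-by-site accumulation", {
  set.seed(71)
  n <- 50L
  calls <- make_calls("chr1", sort(sample.int(1000, n)) - 1L,
                      meth = rbinom(n, 10, 0.3), total = 10,
                      context = sample(c("CpG", "CHH"), n, replace = TRUE))
  region <- list(chrom = "chr1", start = 100, end = 800)
  for (ctx in c("CpG", "CHH")) {
    # brute-force oracle
    m <- 0; t <- 0
    for (i in seq_len(n)) {
      if (calls$context[i] == ctx && calls$pos[i] >= region$start &&
          calls$pos[i] < region$end) {
        m <- m + calls$meth_count[i]; t <- t + calls$total_count[i]
      }
    }
    got <- methylation_level(calls, region, ctx)
    expect_equal(got$level, m / t, tolerance = 1e-12)
    expect_equal(got$coverage, t)
  }
})

test_that("sliding windows tile each chromosome and cover the tail", {
  w <- sliding_windows(c(chrA = 6000L), width = 3000L, step = 600L)
  expect_identical(w$start, seq(0L, 3000L, 600L))
  expect_identical(nrow(w), 6L)
  expect_true(all(w$end - w$start == 3000L))

  w1 <- sliding_windows(c(chrA = 3000L))
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$start, w1$end), c(0L, 3000L))

  # short chromosome: one truncated window
  ws <- sliding_windows(c(chrA = 2000L))
  expect_identical(c(ws$start, ws$end), c(0L, 2000L))

  # non-multiple length: terminal window [L - width, L) appended
  wt <- sliding_windows(c(chrA = 6100L))
  expect_identical(nrow(wt), 7L)
  expect_identical(wt$start[7], 3100L)
  expect_identical(wt$end[7], 6100L)
  expect_identical(max(wt$end), 6100L)  # whole genome covered
})

test_that("window test: null identity and exact doubling-rule p-values", {
  poolA <- data.table::data.table(chrom = "chr1", pos = 0:9, strand = "+",
                                  context = "CHH", meth = 2, total = 4)
  win <- list(chrom = "chr1", start = 0, end = 100)
  r <- test_window(poolA, data.table::copy(poolA), win, context = "CHH")
  expect_equal(r$delta, 0)
  expect_equal(r$p, 1)

  # table [[0,10],[10,0]]: two-sided p = 2 / choose(20, 10)
  pa <- data.table::data.table(chrom = "chr1", pos = 0L, strand = "+",
                               context = "CHH", meth = 0, total = 10)
  pb <- data.table::data.table(chrom = "chr1", pos = 0L, strand = "+",
                               context = "CHH", meth = 10, total = 10)
  r2 <- test_window(pa, pb, win, context = "CHH")
  expect_equal(r2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r2$delta, 1)

  # low coverage is untestable, not significant
  r3 <- test_window(pa, pb, win, context = "CHH", min_cov = 11)
  expect_false(r3$testable)
  expect_true(is.na(r3$p))
})

test_that("doubling-rule p equals full hypergeometric enumeration", {
  doubling_oracle <- function(mA, uA, mB, uB) {
    N <- mA + uA + mB + uB; K <- mA + mB; n <- mA + uA
    xs <- max(0, n - (N - K)):min(n, K)
    pr <- dhyper(xs, K, N - K, n)
    min(1, 2 * min(sum(pr[xs <= mA]), sum(pr[xs >= mA])))
  }
  set.seed(83)
  for (rep in 1:200) {
    tot <- sample(4:40, 1)
    nA <- sample(2:(tot - 2), 1)
    mA <- sample(0:nA, 1); mB <- sample(0:(tot - nA), 1)
    got <- methexpr:::fisher_doubling(mA, nA - mA, mB, tot - nA - mB)
    expect_equal(got, doubling_oracle(mA, nA - mA, mB, tot - nA - mB),
                 tolerance = 1e-12)
    # one-sided tails agree with fisher.test as an independent cross-check
    ft <- fisher.test(matrix(c(mA, nA - mA, mB, tot - nA - mB), 2,
                             byrow = TRUE), alternative = "less")$p.value
    expect_equal(phyper(mA, mA + mB, tot - mA - mB, nA), ft,
                 tolerance = 1e-9)
  }
})

test_that("interval merging is maximal but never joins abutting intervals", {
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(0L, 5L),
                                  end = c(10L, 20L)))
  expect_identical(m$start, 0L)
  expect_identical(m$end, 20L)

  ab <- merge_intervals(data.frame(chrom = "chr1", start = c(0L, 10L),
                                   end = c(10L, 20L)))
  expect_identical(nrow(ab), 2L)  # half-open abutting intervals stay apart

  set.seed(97)
  iv <- random_regions(200, c(chr1 = 5000L, chr2 = 5000L),
                       width_range = c(5L, 200L))
  merged <- merge_intervals(iv)
  # per-base oracle: union cardinality preserved, merged set disjoint
  base_union <- function(d) {
    sum(vapply(unique(d$chrom), function(ch) {
      s <- d[d$chrom == ch, ]
      length(unique(unlist(Map(seq.int, s$start, s$end - 1L))))
    }, numeric(1)))
  }
  expect_equal(base_union(iv), base_union(merged))
  expect_equal(sum(merged$end - merged$start), base_union(merged))
})

test_that("pooling cells then computing levels equals summed counts", {
  set.seed(13)
  cells <- lapply(1:4, function(i) {
    make_calls("chr1", 0:49, meth = rbinom(50, 5, 0.2), total = 5,
               cell_id = paste0("c", i), stage = "GV")
  })
  calls <- data.table::rbindlist(cells)
  pool <- pool_cells(calls)
  region <- list(chrom = "chr1", start = 0, end = 50)
  lev_pool <- sum(pool$meth) / sum(pool$total)
  lev_calls <- methylation_level(calls, region)$level
  expect_equal(lev_pool, lev_calls, tolerance = 1e-12)
  # pooled counts equal the member-cell sums at each site
  site7 <- pool[pool$pos == 7]
  expect_equal(site7$meth, sum(calls[calls$pos == 7]$meth_count))
})

test_that("BH on uniform p-values controls FDR at nominal level", {
  set.seed(29)
  q_nom <- 0.05
  reps <- 1000L
  fdp <- replicate(reps, {
    p <- runif(100)
    rej <- p.adjust(p, "BH") <= q_nom
    as.numeric(any(rej))  # all hypotheses null: FDP is 1 iff any rejection
  })
  mc_se <- sqrt(q_nom * (1 - q_nom) / reps)
  expect_lte(mean(fdp), q_nom + 3 * mc_se)
})

test_that("caller output is invariant to cell and chromosome order", {
  cfg <- small_cfg(n_chroms = 2L, chrom_length = 30000L, n_genes = 6L,
                   n_planted_dmrs = 2L, seed = 61L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  ca <- met$calls[met$calls$stage == "MI"]
  cb <- met$calls[met$calls$stage == "MII"]
  d1 <- call_dmrs(ca, cb, "CHH", ann$chrom_lengths)
  # shuffle rows and reverse chromosome order
  set.seed(1)
  ca2 <- ca[sample(nrow(ca))]
  cb2 <- cb[sample(nrow(cb))]
  d2 <- call_dmrs(ca2, cb2, "CHH", rev(ann$chrom_lengths))
  expect_equal(d1, d2)
})
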