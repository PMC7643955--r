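test_that("PWM construction validates shape and column sums", {
  expect_error(make_pwm("x", matrix(0.25, 4, 3)), "length")
  bad <- matrix(0.3, 4, 6)
  expect_error(make_pwm("x", bad), "sum to 1")
  pw <- make_pwm("ETS1", "ACGGAAGT")
  expect_s3_class(pw, "pwm")
  expect_equal(colSums(pw$mat), rep(1, 8))
})

test_that("consensus PWM scores its motif at the closed-form maximum", {
  # AACC: neither it nor its reverse complement (GGTT) occurs twice below
  mat <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(c("A", "A", "C", "C"), rownames(mat)), 1:4)] <- 1
  pw <- make_pwm("cons", mat)
  expect_equal(pwm_max_score(pw), 8)  # 4 * log2(1 / 0.25)
  hits <- pwm_scan(c(s1 = "TTAACCTT"), pw, threshold_bits = 8)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 2L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$score, 8)

  # the reverse complement of a hit sequence matches on the minus strand
  rc <- pwm_scan(c(s = "TTGGTTTT"), pw, threshold_bits = 8)
  expect_identical(rc$strand, "-")
  expect_identical(rc$start, 2L)
  expect_equal(rc$score, 8)
  pw2 <- pw

  # N bases kill a window; short sequences yield no hits
  expect_identical(nrow(pwm_scan(c(s = "TTAANGTT"), pw2,
                                 threshold_bits = 0)), 0L)
  expect_identical(nrow(pwm_scan(c(s = "AC"), pw2)), 0L)
})

test_that("PWM scan equals exhaustive per-offset scoring on random DNA", {
  set.seed(55)
  seqs <- c(r1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                       collapse = ""))
  mat <- vapply(1:6, function(i) {
    x <- runif(4) + 0.05
    x / sum(x)
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  pw <- make_pwm("rnd", mat)
  thr <- 0.5 * pwm_max_score(pw)
  got <- pwm_scan(seqs, pw, threshold_bits = thr)

  # brute-force oracle: score every offset on both strands
  score_at <- function(s, p) {
    chars <- strsplit(substr(s, p, p + 5L), "")[[1]]
    sum(vapply(1:6, function(i) log2(mat[chars[i], i] / 0.25), numeric(1)))
  }
  s <- seqs[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  exp_rows <- list()
  for (p in 1:(nchar(s) - 5L)) {
    sc <- score_at(s, p)
    if (sc >= thr) exp_rows[[length(exp_rows) + 1L]] <-
        data.frame(start = p - 1L, strand = "+", score = sc)
    scr <- score_at(rc, p)
    if (scr >= thr) exp_rows[[length(exp_rows) + 1L]] <-
        data.frame(start = nchar(s) - (p - 1L) - 6L, strand = "-",
                   score = scr)
  }
  oracle <- do.call(rbind, exp_rows)
  oracle <- oracle[order(oracle$start, oracle$strand), ]
  expect_identical(nrow(got), nrow(oracle))
  expect_identical(got$start, oracle$start)
  expect_identical(got$strand, oracle$strand)
  expect_equal(got$score, oracle$score, tolerance = 1e-9)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[1:5])
  res <- gene_set_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_gte(res$q, res$p)

  # overlap at expectation gives an unremarkable p
  set.seed(66)
  res2 <- gene_set_enrichment(universe[1:10], list(s = universe[6:15]),
                              universe)
  expect_gt(res2$p, 0.4)

  # brute-force tail enumeration for random instances, universe <= 30
  for (rep in 1:50) {
    N <- sample(8:30, 1)
    uni <- sprintf("u%02d", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    set <- sample(uni, K)
    query <- sample(uni, n)
    k <- length(intersect(set, query))
    # P(X >= k) by summing the hypergeometric pmf
    xs <- k:min(K, n)
    oracle <- sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
    got <- gene_set_enrichment(query, list(s = set), uni)$p
    expect_equal(got, oracle, tolerance = 1e-10)
  }

  expect_error(gene_set_enrichment("a", list(s = "a"), character(0)),
               "empty universe")
  expect_error(gene_set_enrichment("zz", list(s = "a"), c("a", "b")),
               "subset")
  # invariant to universe ordering
  expect_equal(gene_set_enrichment(universe[1:5], sets, rev(universe))$p,
               res$p)
})

test_that("gene-body methylation/expression pairs match brute force", {
  cfg <- small_cfg(coverage_rate = 3, seed = 91L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  trx <- simulate_transcriptome(met$annotation, cfg, met$truth)
  fpkm <- compute_fpkm(trx$counts$counts, trx$counts$gene_lengths,
                       merge_by = trx$counts$cell_stage)
  pool <- pool_cells(met$calls)
  pool_mii <- pool[pool$group == "MII"]
  res <- gene_body_meth_expr(pool_mii, fpkm[, "MII"], met$annotation, "CHH",
                             min_cov = 10)
  # brute-force per-gene recomputation
  for (i in seq_len(nrow(res$pairs))) {
    gid <- res$pairs$gene_id[i]
    g <- met$annotation$genes[met$annotation$genes$gene_id == gid, ]
    sel <- pool_mii[pool_mii$chrom == g$chrom & pool_mii$pos >= g$start &
                      pool_mii$pos < g$end & pool_mii$context == "CHH"]
    expect_equal(res$pairs$meth[i], sum(sel$meth) / sum(sel$total),
                 tolerance = 1e-12)
    expect_equal(res$pairs$log_expr[i], log10(fpkm[gid, "MII"] + 1),
                 tolerance = 1e-12)
  }
  expect_true(is.finite(res$r))

  # degenerate constant methylation
  cpool <- data.table::data.table(chrom = "chr1", pos = 0:299, strand = "+",
                                  context = "CHH", meth = 5, total = 10)
  fake_ann <- manual_annotation()
  fake_ann$genes$start <- c(0L, 150L); fake_ann$genes$end <- c(150L, 300L)
  fx <- setNames(c(3, 8), c("g1", "g2"))
  expect_error(gene_body_meth_expr(cpool, fx, fake_ann, "CHH"),
               "fewer than 3")
  fake_ann$genes <- rbind(fake_ann$genes, data.frame(
    gene_id = "g3", chrom = "chr1", strand = "+", start = 0L, end = 300L,
    tss = 0L))
  fx <- c(fx, g3 = 5)
  expect_warning(r0 <- gene_body_meth_expr(cpool, fx, fake_ann, "CHH"),
                 "degenerate")
  expect_true(is.na(r0$r))
})

test_that("DEG / gene-body DMR intersection covers the planted links", {
  cfg <- small_cfg(coverage_rate = 2, n_planted_dmrs = 4L,
                   frac_dmr_genes_up = 1, n_planted_degs = 8L,
                   deg_log2fc_range = c(2, 3), n_cells_per_stage = 8L,
                   seed = 92L)
  ann0 <- simulate_annotation(cfg)
  met <- simulate_methylome(ann0, cfg)
  trx <- simulate_transcriptome(met$annotation, cfg, met$truth)
  ann <- met$annotation
  truth <- trx$truth
  degs <- call_degs(trx$counts, "MI", "MII")
  dmrs <- do.call(rbind, lapply(c("CHG", "CHH"), function(ctx) {
    call_dmrs(met$calls[met$calls$stage == "MI"],
              met$calls[met$calls$stage == "MII"], ctx, ann$chrom_lengths)
  }))
  res <- degs_with_gene_body_dmr(degs, dmrs, ann, direction_filter = "up")
  linked <- unique(truth$dmr_deg_links$gene_id)
  recovered_up <- degs$gene_id[degs$deg & degs$direction == "up"]
  expect_true(all(intersect(linked, recovered_up) %in% res$genes))
  expect_gte(res$tallies[["hyper"]], length(intersect(linked, recovered_up)))

  # trivial cases
  expect_identical(
    degs_with_gene_body_dmr(degs, dmrs[0, ], ann)$fraction, 0)
  whole <- data.frame(chrom = names(ann$chrom_lengths),
                      start = 0L, end = unname(ann$chrom_lengths),
                      context = "CHH", direction = "hyper")
  expect_identical(degs_with_gene_body_dmr(degs, whole, ann)$fraction, 1)
  nodeg <- degs; nodeg$deg <- FALSE
  expect_error(degs_with_gene_body_dmr(nodeg, dmrs, ann), "no DEGs")
})

test_that("TF report flags are conjunctive and tally oracle holds", {
  ann <- manual_annotation()
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 25000), collapse = "")))
  ann$genome <- genome
  expr <- matrix(c(5, 5, 0.2, 0.2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("MI", "MII")))
  dmrs <- data.frame(chrom = "chr1", start = c(11000L, 30000L),
                     end = c(14000L, 33000L), context = "CHH",
                     direction = c("hyper", "hypo"),
                     stringsAsFactors = FALSE)
  pw <- make_pwm("g1", "ACGTACGTAC")  # matches the repeated genome
  # expressed + partner + motif -> triangulated
  rep1 <- tf_triangulate(expr, partner_list = "g1", pwm_set = list(g1 = pw),
                         dmrs = dmrs, genome = genome,
                         annotation = ann)
  expect_true(rep1$triangulated[rep1$tf == "g1"])
  # empty partner list -> nothing triangulated
  rep2 <- tf_triangulate(expr, character(0), list(g1 = pw), dmrs, genome)
  expect_false(any(rep2$triangulated))
  # PWM that cannot hit -> drops out (conjunction semantics)
  pw_miss <- make_pwm("g1", "AAAAAAAAAA")
  rep3 <- tf_triangulate(expr, "g1", list(g1 = pw_miss), dmrs, genome)
  expect_false(any(rep3$triangulated))
  # no PWM -> NA motif flag, message, excluded
  expect_message(
    rep4 <- tf_triangulate(expr, "g2", list(g1 = pw), dmrs, genome),
    "no PWM")
  expect_true(is.na(rep4$motif_in_dmr[rep4$tf == "g2"]))
  expect_false(rep4$triangulated[rep4$tf == "g2"])
  # not expressed -> not triangulated even as partner with motif
  expr0 <- expr; expr0["g1", ] <- 0.1
  rep5 <- tf_triangulate(expr0, "g1", list(g1 = pw), dmrs, genome)
  expect_false(any(rep5$triangulated))

  # direction tally: g1 body [10000,20000) overlaps the hyper DMR with hits
  tl <- tf_target_direction_tally(c("g1", "g2"), dmrs, ann, pw, genome)
  expect_identical(tl$n_with_motif_dmr, 1L)
  expect_identical(tl$n_hyper, 1L)
  # all-hyper DMR set: n_hyper equals n_with_motif_dmr
  dmrs_h <- dmrs; dmrs_h$direction <- "hyper"
  tl2 <- tf_target_direction_tally(c("g1", "g2"), dmrs_h, ann, pw, genome)
  expect_identical(tl2$n_hyper, tl2$n_with_motif_dmr)
  # no motif hits anywhere -> (0, 0)
  tl0 <- tf_target_direction_tally(c("g1", "g2"), dmrs, ann, pw_miss,
                                   genome)
  expect_identical(c(tl0$n_with_motif_dmr, tl0$n_hyper), c(0L, 0L))

  # brute-force triple loop over genes x DMRs x hits
  seqs <- region_sequences(genome, dmrs)
  hits <- pwm_scan(seqs, pw)
  oracle_genes <- character(0); oracle_hyper <- character(0)
  for (gid in c("g1", "g2")) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    for (i in seq_len(nrow(dmrs))) {
      ov <- dmrs$chrom[i] == g$chrom && dmrs$start[i] < g$end &&
        g$start < dmrs$end[i]
      has_hit <- names(seqs)[i] %in% hits$seqname
      if (ov && has_hit) {
        oracle_genes <- union(oracle_genes, gid)
        if (dmrs$direction[i] == "hyper")
          oracle_hyper <- union(oracle_hyper, gid)
      }
    }
  }
  expect_identical(tl$n_with_motif_dmr, length(oracle_genes))
  expect_identical(tl$n_hyper, length(oracle_hyper))
})
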