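test_that("TPM normalisation: definition, ratios, conservation", {
  one <- matrix(7L, 1, 1, dimnames = list("g1", "c1"))
  expect_equal(unname(compute_tpm(one, c(g1 = 1000))[1, 1]), 1e6)

  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  tpm <- compute_tpm(two, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm["g1", 1] / tpm["g2", 1]), 2)

  set.seed(3)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:6)))
  lens <- setNames(sample(500:3000, 10), rownames(m))
  expect_equal(unname(colSums(compute_tpm(m, lens))), rep(1e6, 6),
               tolerance = 1e-6)

  m0 <- m; m0[, 2] <- 0L
  expect_warning(t0 <- compute_tpm(m0, lens), "all-zero")
  expect_true(all(t0[, 2] == 0))
})

test_that("FPKM: definition, scale invariance, merged-stage equivalence", {
  one <- matrix(10L, 1, 1, dimnames = list("g1", "c1"))
  # FPKM = 1e9 * 10 / (1000 * N); make N = 1e6 by adding a filler gene
  m <- rbind(one, matrix(999990L, 1, 1, dimnames = list("filler", "c1")))
  f <- compute_fpkm(m, c(g1 = 1000, filler = 1e5))
  expect_equal(unname(f["g1", 1]), 10)

  expect_equal(compute_fpkm(2L * m, c(g1 = 1000, filler = 1e5)), f)

  set.seed(8)
  counts <- matrix(rpois(80, 30), 10, 8,
                   dimnames = list(sprintf("g%d", 1:10),
                                   sprintf("c%d", 1:8)))
  lens <- setNames(sample(400:4000, 10), rownames(counts))
  stagemap <- setNames(rep(c("GV", "MII"), each = 4), colnames(counts))
  merged <- compute_fpkm(counts, lens, merge_by = stagemap)
  # oracle: sum the counts by hand, then single-library FPKM
  for (st in c("GV", "MII")) {
    summed <- rowSums(counts[, stagemap == st])
    oracle <- 1e9 * summed / (lens * sum(summed))
    expect_equal(unname(merged[, st]), unname(oracle), tolerance = 1e-12)
  }
  expect_error(compute_fpkm(matrix(0L, 2, 1,
                                   dimnames = list(c("a", "b"), "c1")),
                            c(a = 100, b = 100)), "zero total")
})

test_that("expressed and stage-specific sets follow the FPKM >= 1 rule", {
  expr <- matrix(c(2, 0.5, 0.2,
                   1, 1, 0.99,
                   0, 0, 0,
                   5, 5, 5), 4, 3, byrow = TRUE,
                 dimnames = list(c("gvOnly", "boundary", "off", "all"),
                                 c("GV", "MI", "MII")))
  ex <- expressed_set(expr)
  expect_true("boundary" %in% ex$GV)      # FPKM exactly 1 is included
  expect_true("boundary" %in% ex$MI)
  expect_false("boundary" %in% ex$MII)
  expect_false("off" %in% ex$GV)
  # threshold monotonicity
  ex2 <- expressed_set(expr, threshold = 2)
  for (st in colnames(expr)) expect_true(all(ex2[[st]] %in% ex[[st]]))

  sp <- stage_specific(expr)
  expect_identical(sp$GV, "gvOnly")
  expect_false("boundary" %in% unlist(sp))  # expressed in two stages
  expect_false("all" %in% unlist(sp))

  set.seed(14)
  rnd <- matrix(runif(300, 0, 3), 100, 3,
                dimnames = list(sprintf("g%d", 1:100), c("GV", "MI", "MII")))
  sps <- stage_specific(rnd)
  expect_identical(anyDuplicated(unlist(sps)), 0L)  # pairwise disjoint
})

test_that("DEG caller: null identity, symmetry, input validation", {
  set.seed(15)
  base <- matrix(rnbinom(40, mu = 50, size = 10), 10, 4,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:4)))
  dup <- cbind(base, base)
  colnames(dup) <- sprintf("c%d", 1:8)
  stages <- setNames(rep(c("A", "B"), each = 4), colnames(dup))
  r <- call_degs(dup, "A", "B", cell_stage = stages)
  expect_true(all(r$log2fc == 0))
  expect_true(all(r$p == 1))
  expect_false(any(r$deg))

  cfg <- small_cfg(seed = 16L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  cm <- simulate_transcriptome(met$annotation, cfg, met$truth)$counts
  ab <- call_degs(cm, "MI", "MII")
  ba <- call_degs(cm, "MII", "MI")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)

  expect_error(call_degs(cm$counts[, 1:3], "GV", "MI",
                         cell_stage = cm$cell_stage[1:3]),
               ">= 2 cells")
  # genes zero in both groups are excluded from the universe
  z <- dup; z[1, ] <- 0L
  rz <- call_degs(z, "A", "B", cell_stage = stages)
  expect_false("g1" %in% rz$gene_id)
})

test_that("planted log2FC of 2 is estimated within 0.5 at decent depth", {
  cfg <- small_cfg(n_cells_per_stage = 30L, n_planted_degs = 6L,
                   deg_log2fc_range = c(2, 2), n_planted_dmrs = 0L,
                   frac_dmr_genes_up = 0, coverage_rate = 0, seed = 18L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  cm <- simulate_transcriptome(met$annotation, cfg, met$truth)$counts
  truth <- simulate_transcriptome(met$annotation, cfg, met$truth)$truth
  degs <- call_degs(cm, "MI", "MII")
  idx <- match(truth$planted_degs$gene_id, degs$gene_id)
  est <- degs$log2fc[idx]
  # the 0.5 pseudo-mean biases the estimate downward for near-silent genes,
  # so parameter recovery is assessed at adequate expression
  adequate <- degs$base_mean_a[idx] >= 5
  expect_gte(sum(adequate), 3L)
  expect_true(all(abs(est[adequate] - truth$planted_degs$log2fc[adequate])
                  <= 0.5))
})

test_that("DEG calls agree with DESeq2 on a simulated contrast", {
  skip_if_not_installed("DESeq2")
  cfg <- small_cfg(n_cells_per_stage = 8L, n_planted_degs = 6L,
                   deg_log2fc_range = c(2, 3), seed = 26L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  cm <- simulate_transcriptome(met$annotation, cfg, met$truth)$counts
  keep_cells <- names(cm$cell_stage)[cm$cell_stage %in% c("MI", "MII")]
  counts <- cm$counts[, keep_cells]
  cond <- factor(cm$cell_stage[keep_cells], levels = c("MI", "MII"))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, S4Vectors::DataFrame(cond),
                                        ~cond)
  res <- suppressMessages(DESeq2::results(DESeq2::DESeq(dds, quiet = TRUE)))
  ours <- call_degs(cm, "MI", "MII")
  shared <- intersect(rownames(res), ours$gene_id)
  expect_gt(cor(res[shared, "log2FoldChange"],
                ours$log2fc[match(shared, ours$gene_id)]), 0.9)
  ds_deg <- rownames(res)[!is.na(res$padj) & res$padj <= 0.05 &
                            abs(res$log2FoldChange) >= 1]
  our_deg <- ours$gene_id[ours$deg]
  # substantial overlap between the two callers' DEG sets
  expect_gt(length(intersect(ds_deg, our_deg)) /
              max(1, length(union(ds_deg, our_deg))), 0.5)
})

test_that("PCA embedding: variance ordering, duplicates, stage separation", {
  set.seed(44)
  expr <- matrix(rlnorm(600, 3, 1), 100, 6,
                 dimnames = list(sprintf("g%d", 1:100), sprintf("c%d", 1:6)))
  pc <- pca_embedding(expr, top_n = 50L)
  ev <- pc$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(sum(ev), 1)

  dupe <- cbind(expr, dup = expr[, 1])
  pc2 <- pca_embedding(dupe, top_n = 50L)
  expect_equal(unname(pc2$coords["c1", ]), unname(pc2$coords["dup", ]))

  # two stages with a planted mean shift separate on PC1
  cfg <- small_cfg(n_cells_per_stage = 6L, n_planted_degs = 8L,
                   deg_log2fc_range = c(2, 3), seed = 45L)
  ann <- simulate_annotation(cfg)
  met <- simulate_methylome(ann, cfg)
  cm <- simulate_transcriptome(met$annotation, cfg, met$truth)$counts
  tpm <- compute_tpm(cm$counts, cm$gene_lengths)
  emb <- pca_embedding(tpm, top_n = 1000L)
  pc1 <- emb$coords[, 1]
  mature <- cm$cell_stage[rownames(emb$coords)] == "MII"
  # silhouette-like check: MII cells sit on one side of PC1
  sep <- abs(mean(pc1[mature]) - mean(pc1[!mature])) /
    (sd(pc1[mature]) + sd(pc1[!mature]) + 1e-9)
  expect_gt(sep, 1)

  expect_error(pca_embedding(expr[, 1, drop = FALSE]), ">= 2 cells")
})
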