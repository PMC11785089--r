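test_that("log-CPM normalization follows the pseudocount convention", {
  m <- matrix(c(0L, 10L, 990L, 0L, 500L, 500L), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  norm <- normalize_log(m)
  expect_equal(norm["g1", "s1"], 0)  # log2(0 + 1)
  # a count that normalizes to CPM 1 transforms to log2(2) = 1
  m2 <- matrix(c(1L, 999999L), ncol = 1,
               dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_log(m2)["a", "s"], 1)
  # scale invariance: doubling a sample's counts leaves its column unchanged
  m3 <- m; m3[, 1] <- m3[, 1] * 2L
  expect_equal(normalize_log(m3)[, 1], norm[, 1])
  # zero-total sample is an error, not NaN
  m4 <- m; m4[, 2] <- 0L
  expect_error(normalize_log(m4), "zero total")
  # FPKM-like mode rescales by length
  norm_len <- normalize_log(m, gene_lengths = c(g1 = 1000, g2 = 500,
                                                g3 = 2000))
  cpm_g2 <- 10 / 1000 * 1e6
  expect_equal(norm_len["g2", "s1"], log2(cpm_g2 / 0.5 + 1))
})

test_that("fold changes are mean log differences against WT", {
  design <- data.frame(sample_id = c("w1", "w2", "m1", "m2"),
                       genotype = c("WT", "WT", "RdRp_tg", "RdRp_tg"))
  norm <- rbind(gA = c(w1 = 2, w2 = 2, m1 = 4, m2 = 4),
                gB = c(1, 3, 2, 2))
  fc <- fold_changes(norm, design)
  expect_equal(fc["gA", "RdRp_tg"], 2)
  expect_equal(fc["gB", "RdRp_tg"], 0)
  expect_true(all(fc[, "WT"] == 0))
})

test_that("welch statistics agree with stats::t.test and handle degeneracy", {
  set.seed(5)
  design <- data.frame(sample_id = paste0("s", 1:8),
                       genotype = rep(c("WT", "RdRp_Adar_het"), each = 4))
  norm <- matrix(rnorm(80), nrow = 10, ncol = 8,
                 dimnames = list(paste0("g", 1:10), design$sample_id))
  res <- test_differential(norm, design)
  for (i in c(1, 4, 7)) {
    tt <- t.test(norm[i, 5:8], norm[i, 1:4])
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # zero variance in both groups: p = 1 when means equal, 0 otherwise
  norm2 <- rbind(flat = rep(1, 8), shift = rep(c(1, 2), each = 4))
  colnames(norm2) <- design$sample_id
  res2 <- test_differential(norm2, design)
  expect_identical(res2$p[res2$gene == "flat"], 1)
  expect_identical(res2$p[res2$gene == "shift"], 0)
})

test_that("the BH step-up transform behaves as a monotone q-value", {
  # q = min over j >= i of p(j) * m / j; hand case: all four q equal 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  design <- data.frame(sample_id = paste0("s", 1:8),
                       genotype = rep(c("WT", "RdRp_tg"), each = 4))
  set.seed(6)
  norm <- matrix(rnorm(400), nrow = 50, ncol = 8,
                 dimnames = list(paste0("g", 1:50), design$sample_id))
  res <- test_differential(norm, design, c("RdRp_tg", "WT"))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-15))
  expect_true(all(res$q <= 1))
})

test_that("ISG fraction summaries count DEG overlap", {
  isg <- sprintf("isg%02d", 1:50)
  deg <- c(isg[1:10], "other1", "other2")
  r <- classify_isg_fraction(deg, isg)
  expect_identical(r$n_deg, 12L)
  expect_identical(r$n_deg_isg, 10L)
  expect_equal(r$fraction, 10 / 12)
  expect_match(r$summary, "10 out of 12")
  # empty DEG list: undefined fraction
  r2 <- classify_isg_fraction(character(), isg)
  expect_identical(r2$n_deg, 0L)
  expect_true(is.na(r2$fraction))
  # DEG subset of ISG list: fraction 1
  expect_equal(classify_isg_fraction(isg[1:5], isg)$fraction, 1)
  # namespace mismatch warns instead of silently returning zero
  expect_warning(classify_isg_fraction(c("x", "y"), isg), "namespace")
})

test_that("the exact 2x2 test matches enumeration and fisher.test", {
  # every table with margins <= 12 against an independent implementation
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    p <- exact_test_2x2(a, b, cc, d)
    if ((a + b) && (cc + d) && (a + cc) && (b + d)) {
      pf <- fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      expect_equal(p, min(pf, 1), tolerance = 1e-10)
    } else {
      expect_identical(p, 1)
    }
  }
})

test_that("the ISG proportion test builds the table from genic sites only", {
  sites_a <- data.frame(gene_id = c("i1", "i2", NA, "o1", "o2"))
  sites_b <- data.frame(gene_id = c("o3", "o4", NA, NA, "i1", "o5"))
  isg_map <- c(i1 = TRUE, i2 = TRUE, o1 = FALSE, o2 = FALSE, o3 = FALSE,
               o4 = FALSE, o5 = FALSE)
  r <- isg_proportion_test(sites_a, sites_b, isg_map)
  expect_identical(unname(r$table[1, ]), c(2L, 2L))
  expect_identical(unname(r$table[2, ]), c(1L, 3L))
  expect_false(r$untestable)
  expect_equal(r$p, exact_test_2x2(2, 2, 1, 3))
  # odds ratio ad/bc without continuity when no zero cells
  or_plain <- isg_proportion_test(
    data.frame(gene_id = c(rep("i1", 2), rep("o1", 8))),
    data.frame(gene_id = c(rep("i1", 10), rep("o1", 40))), isg_map)
  expect_equal(or_plain$odds_ratio, 1)
  # zero ISG margin: untestable, flagged
  r2 <- isg_proportion_test(data.frame(gene_id = rep("o1", 5)),
                            data.frame(gene_id = rep("o2", 7)), isg_map)
  expect_true(r2$untestable)
  expect_true(is.na(r2$p))
})

test_that("nearest-gene mode classifies intergenic sites by proximity", {
  g <- toy_genome()  # geneP (ISG) at 101-400, geneM at 601-900
  idx <- feature_index(g)
  isg_map <- setNames(g$genes$is_isg, g$genes$gene_id)
  sa <- data.frame(contig = "chr1", pos = c(150L, 420L),
                   gene_id = c("geneP", NA), stringsAsFactors = FALSE)
  sb <- data.frame(contig = "chr1", pos = c(650L, 590L),
                   gene_id = c("geneM", NA), stringsAsFactors = FALSE)
  r <- isg_proportion_test(sa, sb, isg_map, intergenic = "nearest",
                           index = idx)
  # pos 420 joins geneP (ISG); pos 590 joins geneM (non-ISG)
  expect_identical(unname(r$table[1, ]), c(2L, 0L))
  expect_identical(unname(r$table[2, ]), c(0L, 2L))
  # default mode drops the unannotated sites instead
  r2 <- isg_proportion_test(sa, sb, isg_map)
  expect_identical(sum(r2$table), 2L)
})

test_that("null simulation keeps the false discovery rate controlled", {
  set.seed(31)
  design <- data.frame(sample_id = paste0("s", 1:8),
                       genotype = rep(c("WT", "RdRp_Adar_het"), each = 4))
  fdr <- replicate(40, {
    norm <- matrix(rnorm(200 * 8), nrow = 200,
                   dimnames = list(paste0("g", 1:200), design$sample_id))
    res <- test_differential(norm, design)
    disc <- sum(res$q <= 0.05)
    if (disc == 0) 0 else disc / disc  # all discoveries are false
  })
  # mean V / max(R, 1) under the global null
  expect_lte(mean(fdr), 0.07)
})

test_that("planted 8x effects at n = 4 are recovered with high power", {
  set.seed(32)
  design <- data.frame(sample_id = paste0("s", 1:8),
                       genotype = rep(c("WT", "RdRp_Adar_het"), each = 4))
  # planted genes start low (quiescent ISGs), so the 8x induction does not
  # distort library sizes into spurious global downregulation
  n_gene <- 1000; k <- 200
  base <- matrix(rnbinom(n_gene * 8, size = 10, mu = 200), nrow = n_gene)
  base[1:k, 1:4] <- rnbinom(k * 4, size = 10, mu = 25)
  base[1:k, 5:8] <- rnbinom(k * 4, size = 10, mu = 200)
  dimnames(base) <- list(paste0("g", 1:n_gene), design$sample_id)
  res <- expression_summary(base, design, isg_genes = paste0("g", 1:k))
  power <- mean(res$is_deg[1:k] & res$log2fc[1:k] > 0)
  expect_gte(power, 0.8)
  # false flags among the null genes stay rare
  expect_lte(mean(res$is_deg[(k + 1):n_gene]), 0.02)
})

test_that("recovered ISG fold-change tiers preserve the genotype ordering", {
  g <- tiny_genome(seed = 33)
  t <- plant_truth(g, tiny_model(20L), snp_count = 5L, seed = 33)
  d <- sample_design(replicates = 4L)
  cnt <- sim_expression(g, d, t, seed = 33)
  fc <- fold_changes(normalize_log(cnt), d)
  isg <- g$genes$gene_id[g$genes$is_isg]
  m <- colMeans(fc[isg, GENOTYPES])
  expect_true(m[["Adar_het"]] < m[["RdRp_tg"]])
  expect_true(m[["RdRp_tg"]] < m[["RdRp_Adar_het"]])
  expect_equal(m[["WT"]], 0)
})
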