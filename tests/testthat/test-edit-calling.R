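test_that("calling arithmetic and mismatch-class restriction are exact", {
  th <- edit_thresholds(min_coverage = 10L, min_edited = 2L,
                        min_fraction = 0.05, max_fraction = 0.95)
  pu <- data.frame(contig = "chr1", pos = 1:4,
                   ref = c("A", "C", "A", "T"),
                   A = c(8L, 0L, 0L, 1L), C = c(0L, 5L, 0L, 9L),
                   G = c(4L, 0L, 30L, 0L), T = c(0L, 7L, 0L, 20L),
                   stringsAsFactors = FALSE)
  calls <- call_edit_sites(pu, genome = NULL, th)
  # ref A with A=8/G=4: coverage 12, edited 4, fraction 1/3
  expect_identical(nrow(calls), 2L)
  r1 <- calls[calls$pos == 1L, ]
  expect_identical(r1$coverage, 12L)
  expect_identical(r1$edited, 4L)
  expect_equal(r1$fraction, 1 / 3)
  expect_identical(r1$change, "A>G")
  # ref C with T reads is not an A-to-I signature: never emitted
  expect_false(2L %in% calls$pos)
  # ref A, A=0/G=30: fraction 1.0 >= max_fraction, homozygous guard
  expect_false(3L %in% calls$pos)
  # ref T with C=9: T>C retained
  expect_identical(calls$change[calls$pos == 4L], "T>C")
})

test_that("caller output equals a literal brute-force threshold scan", {
  th <- edit_thresholds(min_coverage = 8L, min_edited = 2L,
                        min_fraction = 0.05, max_fraction = 0.95)
  set.seed(101)
  for (rep in 1:40) {
    pu <- random_pileup(sample(50:400, 1))
    got <- call_edit_sites(pu, genome = NULL, th)
    want <- brute_force_calls(pu, th)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$pos, want$pos)
      expect_identical(got$change, want$change)
      expect_equal(got$fraction, want$fraction)
      expect_identical(as.integer(got$coverage), as.integer(want$coverage))
    }
  }
})

test_that("raising thresholds never adds a call (monotonicity)", {
  set.seed(202)
  pu <- random_pileup(2000)
  base <- call_edit_sites(pu, NULL, edit_thresholds(min_coverage = 5L,
                                                    min_edited = 1L))
  key <- function(x) paste(x$contig, x$pos)
  for (mc in c(6L, 8L, 12L)) {
    for (me in c(1L, 2L, 3L)) {
      sub <- call_edit_sites(pu, NULL, edit_thresholds(min_coverage = mc,
                                                       min_edited = me))
      expect_true(all(key(sub) %in% key(base)))
      expect_lte(nrow(sub), nrow(base))
    }
  }
})

test_that("a pileup contradicting the reference is rejected by position", {
  g <- toy_genome()  # all-A reference
  pu <- data.frame(contig = "chr1", pos = c(5L, 6L), ref = c("A", "G"),
                   A = c(10L, 0L), C = 0L, G = c(2L, 10L), T = 0L,
                   stringsAsFactors = FALSE)
  expect_error(call_edit_sites(pu, g), "chr1:6")
  expect_error(call_edit_sites(data.frame(contig = "chr1", pos = 2000L,
                                          ref = "A", A = 1L, C = 0L,
                                          G = 0L, T = 0L), g),
               "outside")
})

test_that("SNP exclusion removes exactly the listed positions, in order", {
  calls <- data.frame(contig = c("chr1", "chr1", "chr2"),
                      pos = c(100L, 200L, 100L),
                      change = "A>G", stringsAsFactors = FALSE)
  snps <- data.frame(contig = "chr1", pos = 100L)
  out <- exclude_snps(calls, snps)
  expect_identical(out$pos, c(200L, 100L))
  expect_identical(out$contig, c("chr1", "chr2"))
  # empty and disjoint SNP sets are no-ops
  expect_identical(exclude_snps(calls, snps[0, ]), calls)
  expect_identical(exclude_snps(calls, data.frame(contig = "chr9",
                                                  pos = 100L)), calls)
})

test_that("SNP exclusion is exact on simulated data across seeds", {
  g <- tiny_genome(seed = 1)
  for (seed in 1:5) {
    t <- plant_truth(g, tiny_model(30L), snp_count = 20L, seed = seed)
    d <- data.frame(sample_id = "s", genotype = "RdRp_Adar_het",
                    replicate = 1L)
    p <- sim_pileups(g, t, d, seed = seed)[[1]]
    calls <- call_edit_sites(p, g)
    final <- orient_edits(exclude_snps(calls, t$snps), g)
    leaked <- paste(final$contig, final$pos) %in%
      paste(t$snps$contig, t$snps$pos)
    expect_identical(sum(leaked), 0L)
  }
})

test_that("strand orientation follows the change/strand decision table", {
  g <- toy_genome()
  # hand-enumerated 2x3 matrix: change {A>G, T>C} x context {+ gene only,
  # - gene only, intergenic}
  calls <- data.frame(
    contig = "chr1",
    pos = c(150L, 650L, 500L, 160L, 660L, 510L),
    change = c("A>G", "A>G", "A>G", "T>C", "T>C", "T>C"),
    stringsAsFactors = FALSE)
  out <- orient_edits(calls, g)
  # A>G in + gene -> +; A>G in - gene only -> dropped; intergenic -> ambiguous
  expect_identical(out$strand[out$pos == 150L], "+")
  expect_false(650L %in% out$pos[out$change == "A>G"])
  expect_identical(out$strand[out$pos == 500L & out$change == "A>G"],
                   "ambiguous")
  # T>C in - gene -> -; T>C in + gene only -> dropped; intergenic -> ambiguous
  expect_identical(out$strand[out$pos == 660L], "-")
  expect_false(160L %in% out$pos[out$change == "T>C"])
  expect_identical(out$strand[out$pos == 510L & out$change == "T>C"],
                   "ambiguous")
  # dialect switch: ambiguous sites dropped on request
  strict <- orient_edits(calls, g, drop_ambiguous = TRUE)
  expect_setequal(strict$pos, c(150L, 660L))
})

test_that("calling recovers planted edits at depth 30 with low error", {
  # depth 30, fraction 0.3, error 0.3%: recall and false discovery
  # proportion over 2,000 planted sites
  g <- sim_genome(seed = 31)
  m <- edit_model(wt_sites = 2000L, shared_fraction = 1, dhet_ratio = 1,
                  adar_het_ratio = 1, rdrp_ratio = 1, fraction_range = 0.3,
                  gene_shared_fraction = 1,
                  gene_private = c(WT = 0, Adar_het = 0, RdRp_tg = 0,
                                   RdRp_Adar_het = 0))
  t <- plant_truth(g, m, snp_count = 50L, seed = 31)
  d <- data.frame(sample_id = "s", genotype = "WT", replicate = 1L)
  p <- sim_pileups(g, t, d, coverage_model(mean_depth = 30),
                   error_rate = 0.003, seed = 31)[[1]]
  final <- orient_edits(exclude_snps(call_edit_sites(p, g), t$snps), g)
  truth_keys <- paste(t$edit_sites$contig, t$edit_sites$pos)
  called_keys <- paste(final$contig, final$pos)
  recall <- mean(truth_keys %in% called_keys)
  fdp <- mean(!(called_keys %in% truth_keys))
  expect_gte(recall, 0.87)
  expect_lte(fdp, 0.08)
})

test_that("threshold constructor rejects inconsistent settings", {
  expect_error(edit_thresholds(min_fraction = 0.9, max_fraction = 0.5))
  expect_error(edit_thresholds(min_coverage = 1L, min_edited = 2L))
})
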