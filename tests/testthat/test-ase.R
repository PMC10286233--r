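test_that("per-SNP acceptance rule enforces all three clauses", {
  # minor < 3
  expect_false(filter_ase_snp(29, 2))
  # boundary: minor 3, total 30, ratio 10%
  expect_true(filter_ase_snp(27, 3))
  # ratio 3/403 = 0.74% < 1%
  expect_false(filter_ase_snp(400, 3))
  # total < 30
  expect_false(filter_ase_snp(20, 5))
  expect_error(filter_ase_snp(-1, 5), "non-negative")
})

test_that("folding is label-symmetric and ties fold to half", {
  expect_equal(fold_counts(10, 10), data.frame(m = 10, d = 20))
  expect_equal(fold_counts(3, 27), fold_counts(27, 3))
  # folding commutes with the generator's swap mechanism: folded counts are
  # a deterministic function of {ref, alt} as a set
  set.seed(2)
  ref <- rpois(200, 40); alt <- rpois(200, 40)
  swap <- runif(200) < 0.5
  ref2 <- ifelse(swap, alt, ref); alt2 <- ifelse(swap, ref, alt)
  expect_identical(fold_counts(ref, alt), fold_counts(ref2, alt2))
})

test_that("the gene statistic is zero at balance and closed-form at full imbalance", {
  # every SNP exactly balanced -> p_hat = 0.5, T = 0
  bal <- ase_statistic(m = c(10, 15), d = c(20, 30),
                       individual = c("i1", "i1"))
  expect_equal(bal$statistic, 0)
  expect_equal(unname(bal$p_hat), 0.5)
  # one individual, one SNP with m = d: T = 2 d log 2
  expect_equal(ase_statistic(40, 40, "i1")$statistic, 2 * 40 * log(2))
  # folded-count contract is validated
  expect_error(ase_statistic(m = 4, d = 10, individual = "i1"), "folded")
})

test_that("the vectorized statistic equals a straight-line reimplementation", {
  gm <- data.frame(gene_id = sprintf("g%02d", 1:10), contig = "1",
                   start = seq(1L, by = 2000L, length.out = 10),
                   end = seq(1L, by = 2000L, length.out = 10) + 999L)
  sim <- simulate_ase_counts(gm, ase_sim_config(
    pi_truth = 0.7, depth_mean = 50, snps_per_gene = 3, seed = 41))
  cnt <- sim$counts
  f <- fold_counts(cnt$ref_reads, cnt$alt_reads)
  for (g in unique(cnt$gene_id)) {
    ix <- cnt$gene_id == g
    got <- ase_statistic(f$m[ix], f$d[ix], cnt$individual[ix])$statistic
    want <- ase_stat_oracle(f$m[ix], f$d[ix], cnt$individual[ix])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a zero observed statistic saturates the null in one batch", {
  res <- ase_test(m = rep(10, 6), d = rep(20, 6),
                  individual = rep(c("i1", "i2"), each = 3),
                  R_max = 10000, batch = 1000, stop_hits = 50, seed = 1)
  expect_equal(res$statistic_T, 0)
  expect_equal(res$resamples_used, 1000)
  expect_gt(res$p_empirical, 0.05)
})

test_that("a strong signal exhausts R_max with zero exceedances", {
  gm <- data.frame(gene_id = "g1", contig = "1", start = 1L, end = 2000L)
  sim <- simulate_ase_counts(gm, ase_sim_config(
    pi_truth = 0.9, depth_mean = 100, snps_per_gene = 5,
    n_individuals = 10, seed = 6))
  f <- fold_counts(sim$counts$ref_reads, sim$counts$alt_reads)
  res <- ase_test(f$m, f$d, sim$counts$individual,
                  R_max = 10000, batch = 1000, stop_hits = 50, seed = 2)
  expect_equal(res$resamples_used, 10000)
  expect_equal(res$p_empirical, 1 / 10001)
})

test_that("the resampling test is deterministic in its seed and validates config", {
  m <- c(30, 25, 28, 22); d <- c(50, 40, 50, 40)
  ind <- c("i1", "i1", "i2", "i2")
  a <- ase_test(m, d, ind, R_max = 2000, seed = 7)
  b <- ase_test(m, d, ind, R_max = 2000, seed = 7)
  expect_identical(a, b)
  expect_error(ase_test(m, d, ind, R_max = 100, batch = 1000), "R_max")
  # p is bounded below by 1/(resamples + 1)
  expect_gte(a$p_empirical, 1 / (a$resamples_used + 1))
})

test_that("BH adjustment matches a textbook step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(31)
  for (k in 1:100) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("mean statistic is monotone in the planted imbalance", {
  gm <- data.frame(gene_id = sprintf("g%02d", 1:30), contig = "1",
                   start = seq(1L, by = 2000L, length.out = 30),
                   end = seq(1L, by = 2000L, length.out = 30) + 999L)
  mean_T <- sapply(c(0.55, 0.65, 0.75, 0.85), function(pi) {
    sim <- simulate_ase_counts(gm, ase_sim_config(
      pi_truth = pi, depth_mean = 50, seed = 55))  # common random numbers
    cnt <- sim$counts
    f <- fold_counts(cnt$ref_reads, cnt$alt_reads)
    mean(sapply(unique(cnt$gene_id), function(g) {
      ix <- cnt$gene_id == g
      ase_statistic(f$m[ix], f$d[ix], cnt$individual[ix])$statistic
    }))
  })
  expect_true(all(diff(mean_T) > 0))
})

test_that("ase_scan is invariant to row order and records skipped genes", {
  gm <- data.frame(gene_id = sprintf("g%02d", 1:8), contig = "1",
                   start = seq(1L, by = 2000L, length.out = 8),
                   end = seq(1L, by = 2000L, length.out = 8) + 999L)
  sim <- simulate_ase_counts(gm, ase_sim_config(
    pi_truth = rep(c(0.5, 0.8), 4), depth_mean = 40, seed = 12))
  cnt <- sim$counts
  # make one gene unacceptable everywhere: deep homozygous-like counts
  ix <- cnt$gene_id == "g01"
  cnt$ref_reads[ix] <- 100L; cnt$alt_reads[ix] <- 0L
  res1 <- ase_scan(cnt, R_max = 500, batch = 250, seed = 3)
  set.seed(77)
  res2 <- ase_scan(cnt[sample.int(nrow(cnt)), ], R_max = 500, batch = 250,
                   seed = 3)
  expect_equal(res1, res2, ignore_attr = TRUE)
  skipped <- attr(res1, "skipped")
  expect_equal(skipped$gene_id, "g01")
  expect_false("g01" %in% res1$gene_id)
  # q values are a within-group BH of the empirical p values
  expect_equal(res1$q_bh, bh_oracle(res1$p_empirical), tolerance = 1e-12)
})
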