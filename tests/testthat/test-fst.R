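test_that("complete fixation gives theta = 1 with a = 1/2, b = c = 0", {
  comp <- wc_components(10, 1, 0, 10, 0, 0)
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(comp$theta, 1)
  # from dosage vectors
  snp <- wc_theta_snp(rep(2L, 10), rep(0L, 10))
  expect_equal(snp$theta, 1)
})

test_that("a SNP monomorphic in the pooled pair has undefined theta", {
  comp <- wc_components(10, 0, 0, 12, 0, 0)
  expect_true(is.na(comp$theta))
  expect_equal(comp$a + comp$b + comp$c, 0)
})

test_that("variance components match an independent scalar oracle", {
  configs <- list(
    list(n1 = 10, p1 = 0.6, h1 = 0.48, n2 = 10, p2 = 0.4, h2 = 0.48),
    list(n1 = 25, p1 = 0.9, h1 = 0.18, n2 = 8, p2 = 0.2, h2 = 0.32),
    list(n1 = 40, p1 = 0.05, h1 = 0.10, n2 = 3, p2 = 0.5, h2 = 1.0))
  for (cf in configs) {
    got <- do.call(wc_components, cf)
    want <- do.call(wc_oracle, cf)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$theta, want$theta, tolerance = 1e-12)
  }
})

test_that("the vectorized per-SNP scan equals the single-SNP path with missing data", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 20, snps_per_gene = 5, missing_rate = 0.2, pop_sizes = 12,
    seed = 17))
  g <- sim$genotypes
  # keep SNPs where both populations retain at least one call
  per_snp <- wc_fst(g, c("LB", "LSL"))
  isA <- g$population == "LB"
  for (i in seq_len(n_snps(g))) {
    dA <- g$dosage[i, isA]; dB <- g$dosage[i, !isA]
    if (all(is.na(dA)) || all(is.na(dB))) {
      expect_true(is.na(per_snp$theta[i]))
      next
    }
    one <- wc_theta_snp(dA, dB)
    expect_equal(per_snp$theta[i], one$theta, tolerance = 1e-12)
    expect_equal(per_snp$a[i], one$a, tolerance = 1e-12)
  }
})

test_that("theta never exceeds 1 and the permuted null centers near zero", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 100, snps_per_gene = 20, baseline_F = 0.1, pop_sizes = 30,
    seed = 19))
  g <- sim$genotypes
  per_snp <- wc_fst(g, c("LB", "LSL"))
  expect_true(all(per_snp$theta <= 1 + 1e-12, na.rm = TRUE))
  # permute population labels: differentiation should vanish
  set.seed(99)
  gp <- g
  gp$population <- sample(g$population)
  perm <- wc_fst(gp, c("LB", "LSL"))
  expect_lt(abs(mean(perm$theta, na.rm = TRUE)), 0.01)
})

test_that("gene aggregation drops thin genes, averages theta, honors overlap", {
  gm <- data.frame(gene_id = c("gA", "gB", "gC"), contig = "1",
                   start = c(100L, 250L, 1000L), end = c(300L, 400L, 1100L),
                   stringsAsFactors = FALSE)
  per_snp <- data.frame(
    id = sprintf("s%d", 1:6), contig = "1",
    pos = c(150L, 260L, 280L, 350L, 1050L, 1060L),
    theta = c(0.1, 0.2, 0.3, 0.4, 0.5, NA))
  res <- aggregate_gene_fst(per_snp, gm, min_snps = 3)
  # gA gets SNPs 1-3 (mean 0.2); gB gets 2-4 (overlap with gA); gC only one
  # defined theta -> dropped
  expect_identical(res$gene_id, c("gA", "gB"))
  expect_equal(res$mean_fst, c(0.2, 0.3))
  expect_equal(res$n_snps, c(3L, 3L))
})

test_that("interval assignment equals brute-force all-pairs containment", {
  set.seed(5)
  n <- 500
  snp <- data.frame(
    contig = sample(c("1", "2"), n, replace = TRUE),
    pos = sample.int(5000, n, replace = TRUE))
  gm <- data.frame(
    gene_id = sprintf("g%03d", 1:60),
    contig = sample(c("1", "2"), 60, replace = TRUE),
    start = sample.int(4500, 60, replace = TRUE))
  gm$end <- gm$start + sample.int(400, 60, replace = TRUE)
  per_snp <- data.frame(id = sprintf("s%03d", 1:n), contig = snp$contig,
                        pos = snp$pos, theta = runif(n))
  res <- aggregate_gene_fst(per_snp, gm, min_snps = 1)
  brute <- brute_gene_assign(snp$contig, snp$pos, gm)
  want <- tapply(per_snp$theta[brute$query], gm$gene_id[brute$subject], mean)
  want_n <- tapply(brute$query, gm$gene_id[brute$subject], length)
  expect_identical(res$gene_id, sort(names(want)))
  expect_equal(res$mean_fst, as.numeric(want[res$gene_id]))
  expect_equal(res$n_snps, as.integer(want_n[res$gene_id]))
})

test_that("Z transform is the sample-sd standardization and rejects degeneracy", {
  zt <- z_transform(c(1, 2, 3))
  expect_equal(zt$z, c(-1, 0, 1))
  expect_equal(zt$mu, 2)
  expect_equal(zt$sigma, 1)
  expect_error(z_transform(c(0.3, 0.3, 0.3)), "degenerate")
  expect_error(z_transform(0.5), "at least 2")
  set.seed(3)
  z <- z_transform(runif(777))$z
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
})

test_that("candidate and top-fraction selection follow threshold and ceil rules", {
  set.seed(11)
  n <- 8929
  res <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                    z_fst = rnorm(n))
  res$z_fst[5] <- 4.0   # boundary: z exactly 4 is a candidate
  res <- select_candidates(res, 4)
  expect_true(res$is_candidate[5])
  res <- select_top_fraction(res, 0.01)
  expect_equal(sum(res$in_top_fraction), ceiling(0.01 * n))
  expect_equal(sum(res$in_top_fraction), 90)
  # top set contains the highest z values
  expect_equal(min(res$z_fst[res$in_top_fraction]),
               sort(res$z_fst, decreasing = TRUE)[90])
  # monotonicity: raising the threshold never adds candidates
  n4 <- sum(select_candidates(res, 4)$is_candidate)
  n5 <- sum(select_candidates(res, 5)$is_candidate)
  expect_lte(n5, n4)
})

test_that("top-fraction ties at the boundary break by gene id", {
  res <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                    z_fst = c(1, 1, 1, 0))
  out <- select_top_fraction(res, 0.5)
  expect_identical(sort(res$gene_id[out$in_top_fraction]), c("gA", "gB"))
})

test_that("planted divergent genes dominate the top of the Z screen", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 400, snps_per_gene = 8, baseline_F = 0.05,
    divergent_gene_fraction = 0.005, divergent_F = 0.5, pop_sizes = 40,
    seed = 23))
  scan <- gene_fst_scan(sim$genotypes, c("LB", "LSL"), sim$gene_map)
  planted <- sim$truth$genes$gene_id[sim$truth$genes$divergent]
  top <- scan$genes$gene_id[scan$genes$in_top_fraction]
  expect_gte(length(intersect(planted, top)) / length(planted), 0.9)
})
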