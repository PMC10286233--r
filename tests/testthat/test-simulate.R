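test_that("cohort configuration invariants are enforced", {
  expect_error(cohort_sim_config(baseline_F = 0), "baseline_F")
  expect_error(cohort_sim_config(baseline_F = 1), "baseline_F")
  expect_error(cohort_sim_config(baseline_F = 0.3, divergent_F = 0.2),
               "exceed baseline_F")
  expect_error(cohort_sim_config(pop_sizes = 1L), "pop_sizes")
  expect_error(cohort_sim_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_sim_config(nonautosomal_fraction = 1.2),
               "nonautosomal_fraction")
})

test_that("cohort simulation is bit-identical for a fixed seed", {
  cfg <- cohort_sim_config(n_genes = 30, snps_per_gene = 4,
                           intergenic_snps = 20, missing_rate = 0.05,
                           nonautosomal_fraction = 0.1, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("cohort structure matches its configuration", {
  cfg <- cohort_sim_config(n_populations = 3, pop_sizes = c(9, 8, 2),
                           n_genes = 25, snps_per_gene = 3,
                           intergenic_snps = 10,
                           divergent_gene_fraction = 0.2, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(n_snps(sim$genotypes), 25 * 3 + 10)
  expect_equal(n_individuals(sim$genotypes), 19)
  expect_equal(sort(unique(sim$genotypes$population)),
               sort(c("LB", "LSL", "BR")))
  expect_equal(nrow(sim$gene_map), 25)
  expect_true(all(sim$gene_map$start <= sim$gene_map$end))
  expect_equal(sum(sim$truth$genes$divergent), round(0.2 * 25))
  expect_equal(sim$truth$genes$true_F[sim$truth$genes$divergent],
               rep(0.5, 5))
  # genic SNP positions fall inside their gene interval
  ts <- sim$truth$snps
  genic <- !is.na(ts$gene_id)
  gm <- sim$gene_map[match(ts$gene_id[genic], sim$gene_map$gene_id), ]
  pos <- sim$genotypes$snps$pos[genic]
  expect_true(all(pos >= gm$start & pos <= gm$end))
})

test_that("multi-locus FST over a uniform-F cohort recovers the Balding-Nichols parameter", {
  cfg <- cohort_sim_config(n_populations = 2, pop_sizes = 50,
                           n_genes = 200, snps_per_gene = 25,
                           baseline_F = 0.2, seed = 7)
  sim <- simulate_cohort(cfg)
  per_snp <- wc_fst(sim$genotypes, c("LB", "LSL"))
  expect_gt(fst_ratio_of_sums(per_snp), 0.17)
  expect_lt(fst_ratio_of_sums(per_snp), 0.23)
})

test_that("QTL region simulation validates inputs and respects the layout", {
  layout <- c("1" = 100000, "2" = 50000)
  expect_error(simulate_qtl_regions(layout, 0), "n_regions")
  expect_error(simulate_qtl_regions(numeric(0), 5), "empty")
  expect_error(simulate_qtl_regions(layout, 5, categories = character(0)),
               "categories")
  regs <- simulate_qtl_regions(layout, 200, mean_length = 3000, seed = 5)
  expect_equal(nrow(regs), 200)
  expect_true(all(regs$category %in% qtl_categories()))
  expect_true(all(regs$start >= 0))
  expect_true(all(regs$end > regs$start))
  expect_true(all(regs$end <= layout[regs$contig]))
  # fixed seed gives identical BED output
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(regs, f1)
  write_bed(simulate_qtl_regions(layout, 200, mean_length = 3000, seed = 5),
            f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null ASE counts are symmetric around one half", {
  gm <- data.frame(gene_id = sprintf("g%03d", 1:100), contig = "1",
                   start = seq(1L, by = 2000L, length.out = 100),
                   end = seq(1L, by = 2000L, length.out = 100) + 999L)
  sim <- simulate_ase_counts(gm, ase_sim_config(pi_truth = 0.5, tau = 0,
                                                depth_mean = 40, seed = 9))
  total <- sum(sim$counts$ref_reads + sim$counts$alt_reads)
  frac <- sum(sim$counts$alt_reads) / total
  se <- sqrt(0.25 / total)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("folded major fraction tracks a strong planted imbalance", {
  gm <- data.frame(gene_id = sprintf("g%02d", 1:20), contig = "1",
                   start = seq(1L, by = 2000L, length.out = 20),
                   end = seq(1L, by = 2000L, length.out = 20) + 999L)
  sim <- simulate_ase_counts(gm, ase_sim_config(pi_truth = 0.9, tau = 0,
                                                depth_mean = 100, seed = 4))
  cnt <- sim$counts
  # per-individual folded fraction, averaged over genes and individuals
  f <- fold_counts(cnt$ref_reads, cnt$alt_reads)
  key <- paste(cnt$gene_id, cnt$individual)
  frac <- tapply(f$m, key, sum) / tapply(f$d, key, sum)
  expect_gt(mean(frac), 0.85)
  expect_lt(mean(frac), 0.95)
  # label swapping hides the direction but not the magnitude
  unfolded <- sum(cnt$alt_reads) / sum(f$d)
  expect_lt(abs(unfolded - 0.5), 0.02)
  expect_gt(sum(f$m) / sum(f$d), 0.85)
})

test_that("ASE simulation is deterministic and validates its configuration", {
  expect_error(ase_sim_config(pi_truth = 0), "pi_truth")
  expect_error(ase_sim_config(tau = -1), "tau")
  expect_error(ase_sim_config(depth_mean = 0), "depth_mean")
  gm <- data.frame(gene_id = "g1", contig = "1", start = 1L, end = 600L)
  cfg <- ase_sim_config(pi_truth = 0.7, seed = 11)
  expect_identical(simulate_ase_counts(gm, cfg),
                   simulate_ase_counts(gm, cfg))
})
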