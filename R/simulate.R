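#' Configuration for the synthetic genotype cohort
#'
#' Describes a Balding--Nichols cohort: each SNP has an ancestral allele
#' frequency drawn uniformly in `[0.05, 0.95]`; each population's frequency is
#' drawn from a Beta distribution with that mean and total shape
#' `(1 - F) / F`, where `F` is the divergence parameter of the SNP's gene
#' (`baseline_F`, or `divergent_F` for planted divergent genes). Under this
#' model `F` is the expectation of the Weir--Cockerham \eqn{\theta}, giving a
#' closed-form recovery target for the estimator.
#'
#' @param n_populations 2 or 3 populations.
#' @param pop_sizes integer vector of diploid individuals per population
#'   (each `>= 2`); recycled from a scalar.
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs tiled within each gene.
#' @param intergenic_snps SNPs placed between genes (background only).
#' @param baseline_F background divergence, in (0, 1).
#' @param divergent_gene_fraction proportion of genes planted as divergent.
#' @param divergent_F divergence of planted genes, in (0, 1) and
#'   `> baseline_F`.
#' @param missing_rate per-call missingness probability, in \[0, 1).
#' @param nonautosomal_fraction probability a SNP is relocated to a sex
#'   contig ("Z" or "W").
#' @param pop_names population labels; defaults to the first
#'   `n_populations` of LB, LSL, BR.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_populations = 2L,
                              pop_sizes = 50L,
                              n_genes = 100L,
                              snps_per_gene = 5L,
                              intergenic_snps = 0L,
                              baseline_F = 0.05,
                              divergent_gene_fraction = 0,
                              divergent_F = 0.5,
                              missing_rate = 0,
                              nonautosomal_fraction = 0,
                              pop_names = NULL,
                              seed = 1L) {
  if (!n_populations %in% c(2L, 3L))
    stop("n_populations must be 2 or 3")
  pop_sizes <- as.integer(rep_len(pop_sizes, n_populations))
  if (any(pop_sizes < 2L)) stop("pop_sizes must all be >= 2")
  if (baseline_F <= 0 || baseline_F >= 1)
    stop("baseline_F must lie strictly in (0, 1)")
  if (divergent_F <= 0 || divergent_F >= 1)
    stop("divergent_F must lie strictly in (0, 1)")
  if (divergent_F <= baseline_F)
    stop("divergent_F must exceed baseline_F")
  if (divergent_gene_fraction < 0 || divergent_gene_fraction > 1)
    stop("divergent_gene_fraction must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (nonautosomal_fraction < 0 || nonautosomal_fraction > 1)
    stop("nonautosomal_fraction must lie in [0, 1]")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (snps_per_gene < 1L) stop("snps_per_gene must be >= 1")
  if (intergenic_snps < 0L) stop("intergenic_snps must be >= 0")
  pop_names <- pop_names %||% c("LB", "LSL", "BR")[seq_len(n_populations)]
  if (length(pop_names) != n_populations) stop("need one name per population")
  structure(list(
    n_populations = as.integer(n_populations), pop_sizes = pop_sizes,
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    intergenic_snps = as.integer(intergenic_snps),
    baseline_F = baseline_F,
    divergent_gene_fraction = divergent_gene_fraction,
    divergent_F = divergent_F, missing_rate = missing_rate,
    nonautosomal_fraction = nonautosomal_fraction,
    pop_names = as.character(pop_names), seed = as.integer(seed)),
    class = "cohort_sim_config")
}

# gene/SNP layout constants: SNP spacing and inter-gene gap, in bases
.SNP_SPACING <- 200L
.GENE_GAP <- 10000L
.N_AUTOSOMES <- 5L

#' Simulate a diploid genotype cohort under the Balding--Nichols model
#'
#' Genes are tiled across five autosomal contigs ("1".."5") with
#' `snps_per_gene` equally spaced SNPs each; intergenic SNPs are placed
#' beyond the gene blocks. A `nonautosomal_fraction` of SNPs is relocated,
#' independently per SNP, to sex contigs "Z"/"W" (these fall outside every
#' gene). Calls are masked to missing independently at `missing_rate`.
#'
#' @param config a [cohort_sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]),
#'   `gene_map` (data.frame: gene_id, contig, start, end — 1-based
#'   inclusive), and `truth` (list with per-gene `genes`: gene_id, true_F,
#'   divergent; and per-SNP `snps`: id, contig_class, gene_id, true_F).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_genes = 10, seed = 7))
#' sim$genotypes
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    config <- do.call(cohort_sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  spg <- config$snps_per_gene
  gene_len <- spg * .SNP_SPACING

  # gene layout: round-robin over autosomes, sequential within a contig
  contig <- as.character(rep_len(seq_len(.N_AUTOSOMES), ng))
  slot <- integer(ng)
  for (k in seq_len(.N_AUTOSOMES)) {
    idx <- which(contig == as.character(k))
    slot[idx] <- seq_along(idx) - 1L
  }
  start <- slot * (gene_len + .GENE_GAP) + 1L
  end <- start + gene_len - 1L
  gene_map <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(ng)),
    contig = contig, start = start, end = end,
    stringsAsFactors = FALSE)

  # genic SNPs: equally spaced inside the gene interval
  snp_gene <- rep(seq_len(ng), each = spg)
  offset <- rep((seq_len(spg) - 1L) * .SNP_SPACING, times = ng)
  snp_contig <- gene_map$contig[snp_gene]
  snp_pos <- gene_map$start[snp_gene] + offset

  # intergenic SNPs: past the last gene block of each contig
  n_ig <- config$intergenic_snps
  if (n_ig > 0L) {
    ig_contig <- as.character(rep_len(seq_len(.N_AUTOSOMES), n_ig))
    ig_pos <- integer(n_ig)
    for (k in seq_len(.N_AUTOSOMES)) {
      ck <- as.character(k)
      base <- max(c(0L, gene_map$end[gene_map$contig == ck])) + .GENE_GAP
      idx <- which(ig_contig == ck)
      ig_pos[idx] <- base + seq_along(idx) * .SNP_SPACING
    }
    snp_contig <- c(snp_contig, ig_contig)
    snp_pos <- c(snp_pos, ig_pos)
    snp_gene <- c(snp_gene, rep(NA_integer_, n_ig))
  }
  n_snp <- length(snp_pos)

  # planted divergent genes
  n_div <- round(config$divergent_gene_fraction * ng)
  div_genes <- sort(sample.int(ng, n_div))
  gene_F <- rep(config$baseline_F, ng)
  gene_F[div_genes] <- config$divergent_F
  snp_F <- ifelse(is.na(snp_gene), config$baseline_F, gene_F[snp_gene])

  # relocate a fraction of SNPs to sex contigs (off every gene)
  nonauto <- runif(n_snp) < config$nonautosomal_fraction
  if (any(nonauto)) {
    idx <- which(nonauto)
    sex <- rep_len(c("Z", "W"), length(idx))
    snp_contig[idx] <- sex
    for (ck in c("Z", "W")) {
      j <- idx[sex == ck]
      snp_pos[j] <- seq_along(j) * .SNP_SPACING
    }
    snp_gene[idx] <- NA_integer_
  }

  # Balding-Nichols frequencies and binomial dosages
  p_anc <- runif(n_snp, 0.05, 0.95)
  shape <- (1 - snp_F) / snp_F
  n_pop <- config$n_populations
  pop_freq <- matrix(0, n_snp, n_pop)
  for (k in seq_len(n_pop))
    pop_freq[, k] <- rbeta(n_snp, p_anc * shape, (1 - p_anc) * shape)

  dosage <- matrix(NA_integer_, n_snp, sum(config$pop_sizes))
  col0 <- 0L
  for (k in seq_len(n_pop)) {
    nk <- config$pop_sizes[k]
    dosage[, col0 + seq_len(nk)] <-
      rbinom(n_snp * nk, 2L, rep(pop_freq[, k], times = nk))
    col0 <- col0 + nk
  }
  if (config$missing_rate > 0)
    dosage[runif(length(dosage)) < config$missing_rate] <- NA_integer_

  individuals <- unlist(lapply(seq_len(n_pop), function(k)
    sprintf("%s_%03d", config$pop_names[k], seq_len(config$pop_sizes[k]))))
  population <- rep(config$pop_names, times = config$pop_sizes)

  ord <- order(snp_contig, snp_pos)
  snps <- data.frame(
    id = sprintf("snp%06d", seq_len(n_snp)),
    contig = snp_contig, pos = as.integer(snp_pos),
    ref = "A", alt = "G", stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(snps) <- NULL

  truth <- list(
    genes = data.frame(
      gene_id = gene_map$gene_id, true_F = gene_F,
      divergent = seq_len(ng) %in% div_genes, stringsAsFactors = FALSE),
    snps = data.frame(
      id = snps$id,
      contig_class = ifelse(snps$contig %in% c("Z", "W"),
                            "nonautosome", "autosome"),
      gene_id = ifelse(is.na(snp_gene[ord]), NA_character_,
                       gene_map$gene_id[snp_gene[ord]]),
      true_F = snp_F[ord], stringsAsFactors = FALSE))

  list(genotypes = genotype_matrix(snps, dosage[ord, , drop = FALSE],
                                   individuals, population),
       gene_map = gene_map, truth = truth)
}

#' Simulate QTL regions across a genome layout
#'
#' Region starts are uniform over the genome (contigs weighted by length),
#' lengths are exponential with mean `mean_length` (at least 1 base, clipped
#' to the contig end), and each region draws a trait category uniformly.
#' Coordinates are 0-based half-open, ready for BED output.
#'
#' @param genome_layout named numeric vector of contig lengths (bases).
#' @param n_regions number of regions (`>= 1`).
#' @param categories non-empty character vector of trait categories.
#' @param mean_length mean region length in bases.
#' @param seed integer seed.
#' @return data.frame: contig, start, end (0-based half-open), category,
#'   source_id.
#' @export
simulate_qtl_regions <- function(genome_layout, n_regions,
                                 categories = qtl_categories(),
                                 mean_length = 5000, seed = 1L) {
  if (length(genome_layout) == 0L) stop("genome layout is empty")
  if (is.null(names(genome_layout)) || any(!nzchar(names(genome_layout))))
    stop("genome layout must be a named vector of contig lengths")
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (length(categories) == 0L) stop("categories must be non-empty")
  set.seed(as.integer(seed))
  contig <- sample(names(genome_layout), n_regions, replace = TRUE,
                   prob = genome_layout / sum(genome_layout))
  len_contig <- genome_layout[contig]
  start <- floor(runif(n_regions, 0, len_contig - 1))
  len <- pmax(1, round(rexp(n_regions, 1 / mean_length)))
  end <- pmin(start + len, len_contig)
  data.frame(
    contig = contig,
    start = as.integer(start), end = as.integer(end),
    category = sample(categories, n_regions, replace = TRUE),
    source_id = sprintf("QTL%05d", seq_len(n_regions)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Configuration for synthetic allelic read counts
#'
#' Emulates unphased per-SNP allelic expression counts per individual: each
#' individual's allelic fraction for a gene is
#' `plogis(qlogis(pi_truth) + rnorm(1, 0, tau))`; per SNP the read depth is
#' Poisson (`depth_mean`, floored at 1) and alternate reads are binomial at
#' the individual's fraction; finally each (SNP, individual) pair has its
#' (ref, alt) labels swapped with probability 1/2, emulating the unknown
#' phase of real unphased data.
#'
#' @param n_individuals individuals per (strain, week) group.
#' @param groups data.frame with columns `strain` and `week`.
#' @param snps_per_gene SNPs measured per gene.
#' @param depth_mean expected reads per SNP per individual (> 0).
#' @param pi_truth per-gene allelic fraction in (0, 1); scalar recycled or
#'   one value per gene. 0.5 is the null.
#' @param tau standard deviation of the per-individual random effect on the
#'   log-odds scale (`>= 0`).
#' @param seed integer seed.
#' @return A validated `ase_sim_config` list.
#' @export
ase_sim_config <- function(n_individuals = 10L,
                           groups = data.frame(strain = "LB", week = 10L),
                           snps_per_gene = 3L,
                           depth_mean = 50,
                           pi_truth = 0.5,
                           tau = 0,
                           seed = 1L) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (!all(c("strain", "week") %in% names(groups)))
    stop("groups needs columns strain and week")
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (snps_per_gene < 1L) stop("snps_per_gene must be >= 1")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (any(pi_truth <= 0 | pi_truth >= 1))
    stop("pi_truth must lie strictly in (0, 1)")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(
    n_individuals = as.integer(n_individuals), groups = groups,
    snps_per_gene = as.integer(snps_per_gene), depth_mean = depth_mean,
    pi_truth = pi_truth, tau = tau, seed = as.integer(seed)),
    class = "ase_sim_config")
}

#' Simulate unphased allelic read counts per gene, group and individual
#'
#' @param gene_map data.frame: gene_id, contig, start, end (1-based
#'   inclusive).
#' @param config an [ase_sim_config()]; `pi_truth` recycled over genes.
#' @return A list with `counts` (data.frame: individual, strain, week,
#'   gene_id, contig, pos, ref_reads, alt_reads) and `truth` (data.frame:
#'   gene_id, pi_truth).
#' @export
#' @examples
#' gm <- data.frame(gene_id = "g1", contig = "1", start = 1L, end = 600L)
#' sim <- simulate_ase_counts(gm, ase_sim_config(pi_truth = 0.8, seed = 3))
#' head(sim$counts)
simulate_ase_counts <- function(gene_map, config) {
  if (!inherits(config, "ase_sim_config"))
    config <- do.call(ase_sim_config, config)
  gene_map <- as.data.frame(gene_map, stringsAsFactors = FALSE)
  if (nrow(gene_map) == 0L) stop("gene map is empty")
  set.seed(config$seed)
  ng <- nrow(gene_map)
  spg <- config$snps_per_gene
  pi_g <- rep_len(config$pi_truth, ng)
  n_grp <- nrow(config$groups)
  n_ind <- config$n_individuals

  # SNP positions: equally spaced within each gene interval
  step <- pmax(1L, (gene_map$end - gene_map$start) %/% spg)
  pos <- gene_map$start[rep(seq_len(ng), each = spg)] +
    rep(seq_len(spg) - 1L, times = ng) * step[rep(seq_len(ng), each = spg)]

  # row layout: group slowest, then individual, then gene, then SNP
  idx_grp <- rep(seq_len(n_grp), each = n_ind * ng * spg)
  idx_ind <- rep(rep(seq_len(n_ind), each = ng * spg), times = n_grp)
  idx_gene <- rep(rep(seq_len(ng), each = spg), times = n_grp * n_ind)
  idx_snp <- rep(seq_len(spg), times = n_grp * n_ind * ng)
  n_row <- length(idx_grp)

  # per (group, individual, gene) allelic fraction with random effect
  n_cell <- n_grp * n_ind * ng
  frac_cell <- plogis(qlogis(rep_len(pi_g, ng)[
    rep(rep(seq_len(ng), times = n_ind), times = n_grp)]) +
      rnorm(n_cell, 0, config$tau))
  cell_of_row <- rep(seq_len(n_cell), each = spg)

  depth <- pmax(1L, rpois(n_row, config$depth_mean))
  alt <- rbinom(n_row, depth, frac_cell[cell_of_row])
  ref <- depth - alt
  swap <- runif(n_row) < 0.5
  alt2 <- ifelse(swap, ref, alt)
  ref2 <- depth - alt2

  counts <- data.frame(
    individual = sprintf("%s_w%s_i%02d", config$groups$strain[idx_grp],
                         config$groups$week[idx_grp], idx_ind),
    strain = config$groups$strain[idx_grp],
    week = config$groups$week[idx_grp],
    gene_id = gene_map$gene_id[idx_gene],
    contig = gene_map$contig[idx_gene],
    pos = as.integer(pos[(idx_gene - 1L) * spg + idx_snp]),
    ref_reads = as.integer(ref2), alt_reads = as.integer(alt2),
    stringsAsFactors = FALSE)
  list(counts = counts,
       truth = data.frame(gene_id = gene_map$gene_id, pi_truth = pi_g,
                          stringsAsFactors = FALSE))
}
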