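# Independent oracles: straight-line scalar implementations used only to
# check the package's vectorized code paths. Kept deliberately naive.

# Weir-Cockerham two-population variance components from per-population
# summaries; scalar, transcribed term by term.
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 / (r * n_bar) + n2^2 / (r * n_bar))) / (r - 1)
  p_bar <- (n1 * p1) / (r * n_bar) + (n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2) / ((r - 1) * n_bar) +
    (n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1) / (r * n_bar) + (n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom == 0) NA_real_ else a / denom)
}

# brute-force SNP-in-gene containment (1-based inclusive), all pairs
brute_gene_assign <- function(snp_contig, snp_pos, gm) {
  out <- list()
  for (i in seq_along(snp_pos)) {
    for (j in seq_len(nrow(gm))) {
      if (snp_contig[i] == gm$contig[j] &&
          snp_pos[i] >= gm$start[j] && snp_pos[i] <= gm$end[j]) {
        out[[length(out) + 1L]] <- data.frame(query = i, subject = j)
      }
    }
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  do.call(rbind, out)
}

# brute-force SNP-in-QTL containment: 1-based VCF pos p against 0-based
# half-open [start, end): start <= p - 1 < end
brute_coloc <- function(snps, regions) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(regions))) {
      b <- snps$pos[i] - 1L
      if (snps$contig[i] == regions$contig[j] &&
          b >= regions$start[j] && b < regions$end[j]) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = snps$gene_id[i], pos = snps$pos[i],
          source_id = regions$source_id[j],
          category = regions$category[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), pos = integer(),
                      source_id = character(), category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# textbook Benjamini-Hochberg step-up with monotonicity enforcement
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  if (m > 1) {
    for (i in (m - 1):1) {
      q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1]])
    }
  }
  q
}

# straight-line folded deviance statistic: loops over individuals and SNPs
ase_stat_oracle <- function(m, d, individual) {
  total <- 0
  for (ind in unique(individual)) {
    ix <- individual == ind
    phat <- sum(m[ix]) / sum(d[ix])
    dev <- 0
    for (s in which(ix)) {
      t1 <- if (m[s] > 0) m[s] * log(phat) else 0
      t2 <- if (d[s] - m[s] > 0) (d[s] - m[s]) * log(1 - phat) else 0
      dev <- dev + t1 + t2 - d[s] * log(0.5)
    }
    total <- total + 2 * dev
  }
  total
}

# small genotype fixture with explicit dosages
make_geno <- function(dosage, contig = NULL, pos = NULL, population) {
  dosage <- as.matrix(dosage)
  ns <- nrow(dosage)
  genotype_matrix(
    snps = data.frame(
      id = sprintf("s%03d", seq_len(ns)),
      contig = contig %||% rep("1", ns),
      pos = pos %||% seq_len(ns) * 100L,
      ref = "A", alt = "G", stringsAsFactors = FALSE),
    dosage = dosage,
    individuals = sprintf("i%03d", seq_len(ncol(dosage))),
    population = population)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
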