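#' Weir--Cockerham variance components from per-population summaries
#'
#' Method-of-moments components for `r = 2` populations from per-population
#' non-missing diploid sample sizes `n_i`, alternate-allele frequencies
#' `p_i` and observed heterozygote proportions `h_i`:
#' \deqn{\bar n = (n_1 + n_2)/2,\quad
#'       n_c = (2\bar n - (n_1^2 + n_2^2)/(2\bar n))/(r - 1)}
#' \deqn{\bar p = \sum n_i p_i / (2\bar n),\quad
#'       s^2 = \sum n_i (p_i - \bar p)^2 / ((r-1)\bar n),\quad
#'       \bar h = \sum n_i h_i / (2\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}
#'       \big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p)
#'       - \tfrac{r-1}{r}s^2 - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad
#'       c = \bar h / 2}
#' and \eqn{\theta = a/(a+b+c)}, undefined (`NA`) when `a + b + c = 0`
#' (e.g. a SNP monomorphic in the pooled pair). Negative \eqn{\theta} values
#' are retained, not truncated.
#'
#' All arguments are vectorized over SNPs.
#'
#' @param n1,n2 non-missing diploid sample sizes (`> 0`; `n_bar > 1`).
#' @param p1,p2 alternate-allele frequencies in \[0, 1\].
#' @param h1,h2 observed heterozygote proportions in \[0, 1\].
#' @return data.frame: n1, p1, h1, n2, p2, h2, n_bar, n_c, p_bar, s2,
#'   h_bar, a, b, c, theta.
#' @export
#' @examples
#' # complete fixation: theta = 1
#' wc_components(10, 1, 0, 10, 0, 0)$theta
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  k <- max(length(n1), length(n2), length(p1), length(p2),
           length(h1), length(h2))
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  p1 <- rep_len(p1, k); p2 <- rep_len(p2, k)
  h1 <- rep_len(h1, k); h2 <- rep_len(h2, k)
  r <- 2
  n_bar <- (n1 + n2) / r
  bad <- n1 <= 0 | n2 <= 0 | n_bar <= 1
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  out <- data.frame(n1 = n1, p1 = p1, h1 = h1, n2 = n2, p2 = p2, h2 = h2,
                    n_bar = n_bar, n_c = n_c, p_bar = p_bar, s2 = s2,
                    h_bar = h_bar, a = a, b = b, c = cc, theta = theta)
  if (any(bad))
    out[bad, c("n_c", "p_bar", "s2", "h_bar", "a", "b", "c", "theta")] <-
      NA_real_
  out
}

#' Weir--Cockerham theta for one SNP from two dosage vectors
#'
#' Summarizes each population's non-missing dosages (sample size, alternate
#' frequency, heterozygote proportion) and evaluates [wc_components()].
#'
#' @param dos1,dos2 diploid dosage vectors (0/1/2, `NA` missing) for the
#'   two populations.
#' @return One-row data.frame of Weir--Cockerham components (see
#'   [wc_components()]).
#' @export
wc_theta_snp <- function(dos1, dos2) {
  n1 <- sum(!is.na(dos1)); n2 <- sum(!is.na(dos2))
  if (n1 == 0L || n2 == 0L)
    stop("a population has all calls missing for this SNP")
  if ((n1 + n2) / 2 <= 1)
    stop("mean sample size must exceed 1")
  wc_components(
    n1, sum(dos1, na.rm = TRUE) / (2 * n1), mean(dos1 == 1L, na.rm = TRUE),
    n2, sum(dos2, na.rm = TRUE) / (2 * n2), mean(dos2 == 1L, na.rm = TRUE))
}

#' Per-SNP Weir--Cockerham theta for a population pair
#'
#' Vectorized over all SNPs of a genotype matrix. SNPs with no non-missing
#' call in either population, or with mean sample size `<= 1`, get `NA`
#' components (such SNPs are normally removed by [filter_snps()] first).
#'
#' @param g a [genotype_matrix()].
#' @param pops character vector of the two population labels.
#' @return data.frame: id, contig, pos, then the [wc_components()] columns.
#' @export
wc_fst <- function(g, pops) {
  stopifnot(inherits(g, "genotype_matrix"), length(pops) == 2L)
  if (!all(pops %in% g$population))
    stop("population(s) absent from the cohort: ",
         paste(setdiff(pops, g$population), collapse = ", "))
  stat <- function(pop) {
    sub <- g$dosage[, g$population == pop, drop = FALSE]
    n <- rowSums(!is.na(sub))
    list(n = n,
         p = rowSums(sub, na.rm = TRUE) / (2 * n),
         h = rowSums(sub == 1L, na.rm = TRUE) / n)
  }
  s1 <- stat(pops[1L]); s2 <- stat(pops[2L])
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  cbind(g$snps[, c("id", "contig", "pos")], comp, row.names = NULL)
}

#' Multi-locus ratio-of-sums FST estimate
#'
#' \eqn{\hat\theta = \sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)}
#' over loci with defined components and a nonzero pooled denominator — the
#' statistically preferred multi-locus combination (averaging per-locus
#' ratios is noisier and biased at low-information loci).
#'
#' @param per_snp data.frame from [wc_fst()] (needs columns a, b, c).
#' @return Numeric scalar estimate.
#' @export
fst_ratio_of_sums <- function(per_snp) {
  ok <- !is.na(per_snp$a) & !is.na(per_snp$b) & !is.na(per_snp$c) &
    (per_snp$a + per_snp$b + per_snp$c) != 0
  sum(per_snp$a[ok]) / sum(per_snp$a[ok] + per_snp$b[ok] + per_snp$c[ok])
}

#' Aggregate per-SNP theta to gene level
#'
#' A SNP belongs to a gene iff its 1-based position lies in the gene's
#' `[start, end]` inclusive on the same contig; SNPs in overlapping genes
#' contribute to each. Undefined thetas are excluded before counting; genes
#' with fewer than `min_snps` defined thetas are dropped. Two aggregation
#' modes: the arithmetic `"mean"` of per-SNP theta (default), or the
#' multi-locus `"ratio_of_sums"` estimate over the gene's SNPs.
#'
#' @param per_snp data.frame from [wc_fst()] (columns contig, pos, theta
#'   and, for the ratio mode, a, b, c).
#' @param gene_map data.frame: gene_id, contig, start, end.
#' @param min_snps minimum number of defined-theta SNPs per gene.
#' @param mode `"mean"` or `"ratio_of_sums"`.
#' @return data.frame: gene_id, contig, start, end, n_snps, mean_fst,
#'   ordered by gene_id.
#' @export
aggregate_gene_fst <- function(per_snp, gene_map, min_snps = 3L,
                               mode = c("mean", "ratio_of_sums")) {
  mode <- match.arg(mode)
  gene_map <- as.data.frame(gene_map, stringsAsFactors = FALSE)
  if (nrow(gene_map) == 0L) stop("gene map is empty")
  snp <- per_snp[!is.na(per_snp$theta), , drop = FALSE]
  hits <- interval_hits(snp$contig, snp$pos, snp$pos,
                        gene_map$contig, gene_map$start, gene_map$end)
  if (nrow(hits) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), mean_fst = numeric(),
                      stringsAsFactors = FALSE))
  gi <- hits$subject
  agg <- if (mode == "mean") {
    tapply(snp$theta[hits$query], gi, mean)
  } else {
    num <- tapply(snp$a[hits$query], gi, sum)
    den <- tapply((snp$a + snp$b + snp$c)[hits$query], gi, sum)
    num / den
  }
  n_by_gene <- tapply(hits$query, gi, length)
  idx <- as.integer(names(agg))
  out <- data.frame(gene_id = gene_map$gene_id[idx],
                    contig = gene_map$contig[idx],
                    start = gene_map$start[idx], end = gene_map$end[idx],
                    n_snps = as.integer(n_by_gene),
                    mean_fst = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 1-based inclusive point/interval containment via IRanges.
# Returns data.frame(query = point index, subject = interval index).
interval_hits <- function(q_contig, q_start, q_end,
                          s_contig, s_start, s_end) {
  out <- list()
  for (ck in unique(q_contig)) {
    qi <- which(q_contig == ck)
    si <- which(s_contig == ck)
    if (!length(qi) || !length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi], q_end[qi]),
      IRanges::IRanges(s_start[si], s_end[si]))
    out[[ck]] <- data.frame(query = qi[S4Vectors::queryHits(ov)],
                            subject = si[S4Vectors::subjectHits(ov)])
  }
  if (!length(out))
    return(data.frame(query = integer(), subject = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Z-standardize gene-level FST values
#'
#' \eqn{Z_g = (\bar F_{ST,g} - \mu)/\sigma} with \eqn{\mu} the mean and
#' \eqn{\sigma} the sample (n-1) standard deviation over gene-level values.
#'
#' @param gene_means numeric vector of gene-level FST values (length >= 2).
#' @return list: `z` (scores), `mu`, `sigma`.
#' @export
#' @examples
#' z_transform(c(1, 2, 3))$z
z_transform <- function(gene_means) {
  if (length(gene_means) < 2L) stop("need at least 2 gene-level values")
  mu <- mean(gene_means)
  sigma <- sd(gene_means)
  if (sigma == 0) stop("degenerate screen: all gene-level FST values equal")
  list(z = (gene_means - mu) / sigma, mu = mu, sigma = sigma)
}

#' Flag candidate genes by Z(FST) threshold
#'
#' @param results data.frame with a `z_fst` column.
#' @param z_threshold candidates satisfy `z_fst >= z_threshold` (boundary
#'   inclusive).
#' @return `results` with a logical `is_candidate` column.
#' @export
select_candidates <- function(results, z_threshold = 4) {
  results$is_candidate <- results$z_fst >= z_threshold
  results
}

#' Flag the top fraction of genes by Z(FST)
#'
#' Ranks by `z_fst` descending, ties broken by `gene_id` lexicographically
#' ascending, and flags exactly `ceiling(fraction * n_genes)` genes.
#'
#' @param results data.frame with `z_fst` and `gene_id` columns.
#' @param fraction fraction in (0, 1].
#' @return `results` with a logical `in_top_fraction` column.
#' @export
select_top_fraction <- function(results, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(results)
  k <- ceiling(fraction * n)
  ord <- order(-results$z_fst, results$gene_id)
  flag <- logical(n)
  flag[ord[seq_len(min(k, n))]] <- TRUE
  results$in_top_fraction <- flag
  results
}

#' Gene-level FST scan for one population pair
#'
#' Composes [wc_fst()], [aggregate_gene_fst()], [z_transform()],
#' [select_candidates()] and [select_top_fraction()] on an already filtered
#' genotype matrix.
#'
#' @param g filtered [genotype_matrix()].
#' @param pops the two population labels.
#' @param gene_map data.frame: gene_id, contig, start, end.
#' @param min_snps minimum defined-theta SNPs per gene.
#' @param z_threshold candidate threshold on Z(FST).
#' @param top_fraction top-set fraction.
#' @param mode gene aggregation mode (see [aggregate_gene_fst()]).
#' @return list: `genes` (data.frame with z_fst and flags), `per_snp`
#'   (the [wc_fst()] table), `mu`, `sigma`.
#' @export
gene_fst_scan <- function(g, pops, gene_map, min_snps = 3L, z_threshold = 4,
                          top_fraction = 0.01, mode = "mean") {
  per_snp <- wc_fst(g, pops)
  genes <- aggregate_gene_fst(per_snp, gene_map, min_snps, mode)
  zt <- z_transform(genes$mean_fst)
  genes$z_fst <- zt$z
  genes <- select_candidates(genes, z_threshold)
  genes <- select_top_fraction(genes, top_fraction)
  list(genes = genes, per_snp = per_snp, mu = zt$mu, sigma = zt$sigma)
}
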