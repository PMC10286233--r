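#' Per-SNP acceptance rule for allelic read counts
#'
#' A (SNP, sample) observation is accepted iff, with
#' `minor = min(ref, alt)` and `total = ref + alt`:
#' `minor >= min_minor_count`, `total >= min_total`, and
#' `minor / total >= min_minor_ratio`. Defaults: minor allele count of at
#' least 3 reads, total of at least 30 reads, minor allele ratio of at
#' least 1%.
#'
#' @param min_minor_count minimum minor-allele read count.
#' @param min_total minimum total read depth at the SNP.
#' @param min_minor_ratio minimum minor-allele read fraction.
#' @return An `ase_filter_rule` list.
#' @export
ase_filter_rule <- function(min_minor_count = 3L, min_total = 30L,
                            min_minor_ratio = 0.01) {
  if (min_minor_count <= 0 || min_total <= 0 || min_minor_ratio <= 0)
    stop("filter thresholds must be positive")
  structure(list(min_minor_count = as.integer(min_minor_count),
                 min_total = as.integer(min_total),
                 min_minor_ratio = min_minor_ratio),
            class = "ase_filter_rule")
}

#' @rdname ase_filter_rule
#' @param ref_reads,alt_reads non-negative read counts (vectorized).
#' @param rule an `ase_filter_rule`.
#' @return `filter_ase_snp()`: logical acceptance flag per observation.
#' @export
#' @examples
#' filter_ase_snp(c(29, 27, 400), c(2, 3, 3))
filter_ase_snp <- function(ref_reads, alt_reads, rule = ase_filter_rule()) {
  if (any(ref_reads < 0) || any(alt_reads < 0))
    stop("read counts must be non-negative")
  minor <- pmin(ref_reads, alt_reads)
  total <- ref_reads + alt_reads
  minor >= rule$min_minor_count & total >= rule$min_total &
    minor / total >= rule$min_minor_ratio
}

#' Fold unphased allelic counts to the major allele
#'
#' Per SNP observation: depth `d = ref + alt` and folded major count
#' `m = max(ref, alt)`, so `m >= d / 2` always and the result is invariant
#' to (ref, alt) label swaps — the package's treatment of unphased data.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorized).
#' @return data.frame: m (major count), d (depth).
#' @export
fold_counts <- function(ref_reads, alt_reads) {
  data.frame(m = pmax(ref_reads, alt_reads), d = ref_reads + alt_reads)
}

# Core folded-deviance computation shared by the observed statistic and the
# resampling null, so both take the identical floating-point path.
# m: S x B matrix of folded major counts (columns = replicates);
# d: length-S depths; ind: length-S individual grouping.
# Returns a length-B vector of T values.
.folded_deviance_T <- function(m, d, ind) {
  ind <- as.factor(ind)
  M <- rowsum(m, ind)                      # J x B major-count sums
  D <- as.vector(rowsum(d, ind))           # J depths
  phat <- M / D
  t1 <- M * log(phat)                      # phat >= 0.5, log finite
  t2 <- (D - M) * log(1 - phat)
  t2[(D - M) == 0] <- 0                    # 0 * log(0) := 0
  colSums(2 * (t1 + t2 - D * log(0.5)))
}

#' Folded binomial deviance statistic for one gene in one group
#'
#' Per individual `j` with accepted SNPs `s`: the pooled major fraction is
#' `p_j = sum(m_s) / sum(d_s)` (always `>= 0.5`) and the deviance against
#' the balanced null is
#' `2 * sum(m_s log p_j + (d_s - m_s) log(1 - p_j) - d_s log 0.5)` with the
#' convention `0 log 0 = 0`. The gene statistic is `T = sum_j deviance_j`,
#' which is non-negative because `p_j` is the maximizer of the folded
#' binomial likelihood.
#'
#' @param m folded major counts per accepted SNP observation.
#' @param d depths per observation.
#' @param individual individual label per observation.
#' @return list: `statistic` (T), `n_individuals`, `p_hat` (named
#'   per-individual pooled major fractions).
#' @export
#' @examples
#' # one individual, one completely imbalanced SNP: T = 2 d log 2
#' ase_statistic(m = 40, d = 40, individual = "i1")$statistic
#' 2 * 40 * log(2)
ase_statistic <- function(m, d, individual) {
  if (length(m) == 0L) stop("no accepted SNP observations")
  if (any(m < d / 2) || any(m > d))
    stop("m must satisfy d/2 <= m <= d (folded counts)")
  ind <- as.factor(individual)
  M <- as.vector(rowsum(m, ind))
  D <- as.vector(rowsum(d, ind))
  list(statistic = unname(.folded_deviance_T(matrix(m, ncol = 1L), d, ind)),
       n_individuals = nlevels(ind),
       p_hat = stats::setNames(M / D, levels(ind)))
}

#' Resampling test of gene-level allelic imbalance in a population
#'
#' The null model holds each observation's depth fixed and redraws the
#' pre-folding count symmetrically: `x* ~ Binomial(d_s, 1/2)`, folded to
#' `m* = max(x*, d_s - x*)`, after which the statistic is recomputed.
#' Resamples are processed in batches of `batch`; the test stops early once
#' `stop_hits` resamples have reached `T* >= T_obs` (a fixed-hits rule
#' bounding the relative Monte-Carlo error of the p estimate) or after
#' `R_max` resamples. The empirical p-value is
#' `(1 + hits) / (1 + resamples_used)`, which is never 0 and is valid by
#' construction because the null applies the identical folding and
#' statistic.
#'
#' @param m,d,individual folded data for one gene and one group (see
#'   [ase_statistic()]).
#' @param R_max maximum number of resamples.
#' @param batch resamples per batch (`<= R_max`).
#' @param stop_hits early-stopping hit count.
#' @param seed integer seed for this gene's resampling substream.
#' @return list: statistic_T, n_individuals_used, resamples_used,
#'   p_empirical.
#' @export
ase_test <- function(m, d, individual, R_max = 10000L, batch = 1000L,
                     stop_hits = 50L, seed = 1L) {
  if (R_max < batch) stop("R_max must be >= batch")
  if (batch < 1L || stop_hits < 1L) stop("batch and stop_hits must be >= 1")
  obs <- ase_statistic(m, d, individual)
  T_obs <- obs$statistic
  ind <- as.factor(individual)
  S <- length(d)
  eps <- 1e-9 * max(1, T_obs)

  set.seed(as.integer(seed))
  hits <- 0L
  used <- 0L
  while (used < R_max) {
    B <- min(batch, R_max - used)
    x <- matrix(rbinom(S * B, size = d, prob = 0.5), nrow = S)
    mstar <- pmax(x, d - x)
    Tstar <- .folded_deviance_T(mstar, d, ind)
    hits <- hits + sum(Tstar >= T_obs - eps)
    used <- used + B
    if (hits >= stop_hits) break
  }
  list(statistic_T = T_obs, n_individuals_used = obs$n_individuals,
       resamples_used = used, p_empirical = (1 + hits) / (1 + used))
}

#' Benjamini--Hochberg adjusted q-values
#'
#' Standard step-up procedure with monotonicity enforcement, as implemented
#' by [stats::p.adjust()] with `method = "BH"`; applied within one
#' (strain, week) group of gene-level tests.
#'
#' @param p vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Population-level ASE detection across genes and groups
#'
#' Applies the per-SNP acceptance rule, folds counts, computes the gene
#' statistic and resampling p-value per (gene, strain, week), and adjusts
#' p-values by Benjamini--Hochberg within each (strain, week) group. Each
#' gene draws its resamples from a named substream of `seed`, so results do
#' not depend on gene evaluation order. Genes whose observations are all
#' rejected by the filter in a group are recorded in the `skipped`
#' attribute.
#'
#' Significance flags: `significant_05` is `p_empirical < 0.05`;
#' `significant_01` is `p_empirical < 0.01` together with BH q-value below
#' `fdr_level`.
#'
#' @param counts ASE count table (see [read_ase_counts()] for the schema).
#' @param rule an [ase_filter_rule()].
#' @param R_max,batch,stop_hits resampling controls (see [ase_test()]).
#' @param seed base seed.
#' @param fdr_level FDR level for the `significant_01` flag.
#' @return data.frame: gene_id, strain, week, n_individuals_used,
#'   statistic_T, resamples_used, p_empirical, q_bh, significant_05,
#'   significant_01 — ordered by strain, week, gene_id. Attribute
#'   `skipped`: data.frame of (gene_id, strain, week) with no accepted SNP.
#' @export
ase_scan <- function(counts, rule = ase_filter_rule(), R_max = 10000L,
                     batch = 1000L, stop_hits = 50L, seed = 1L,
                     fdr_level = 0.05) {
  req <- c("individual", "strain", "week", "gene_id", "ref_reads",
           "alt_reads")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("counts is missing columns: ",
                         paste(miss, collapse = ", "))
  accept <- filter_ase_snp(counts$ref_reads, counts$alt_reads, rule)
  kept <- counts[accept, , drop = FALSE]

  all_keys <- unique(counts[, c("gene_id", "strain", "week")])
  kept_keys <- unique(kept[, c("gene_id", "strain", "week")])
  skipped <- all_keys[!do.call(paste, all_keys) %in%
                        do.call(paste, kept_keys), , drop = FALSE]
  rownames(skipped) <- NULL

  if (nrow(kept) == 0L) {
    out <- data.frame(gene_id = character(), strain = character(),
                      week = integer(), n_individuals_used = integer(),
                      statistic_T = numeric(), resamples_used = integer(),
                      p_empirical = numeric(), q_bh = numeric(),
                      significant_05 = logical(), significant_01 = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }

  fold <- fold_counts(kept$ref_reads, kept$alt_reads)
  key <- interaction(kept$strain, kept$week, kept$gene_id, drop = TRUE,
                     sep = "\r")
  parts <- split(seq_len(nrow(kept)), key)
  rows <- lapply(parts, function(ix) {
    # canonical within-gene row order so results are invariant to the
    # input row order of the count table
    ix <- if (!is.null(kept$pos)) {
      ix[order(kept$individual[ix], kept$contig[ix], kept$pos[ix])]
    } else {
      ix[order(kept$individual[ix])]
    }
    g <- kept$gene_id[ix[1L]]
    s <- kept$strain[ix[1L]]
    w <- kept$week[ix[1L]]
    res <- ase_test(fold$m[ix], fold$d[ix], kept$individual[ix],
                    R_max = R_max, batch = batch, stop_hits = stop_hits,
                    seed = substream_seed(seed, paste("ase", s, w, g)))
    data.frame(gene_id = g, strain = s, week = w,
               n_individuals_used = res$n_individuals_used,
               statistic_T = res$statistic_T,
               resamples_used = res$resamples_used,
               p_empirical = res$p_empirical, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$week, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL

  out$q_bh <- NA_real_
  for (grp in unique(paste(out$strain, out$week))) {
    ix <- paste(out$strain, out$week) == grp
    out$q_bh[ix] <- bh_adjust(out$p_empirical[ix])
  }
  out$significant_05 <- out$p_empirical < 0.05
  out$significant_01 <- out$p_empirical < 0.01 & out$q_bh < fdr_level
  attr(out, "skipped") <- skipped
  out
}
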