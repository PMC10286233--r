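#' SNP filter accounting ledger
#'
#' Integer-conserving record of the retention pipeline:
#' `total_input - removed_call_rate - removed_nonautosomal -
#' removed_monomorphic_or_low_maf = retained`. The constructor computes
#' `retained` and rejects any negative entry, so the identity holds on every
#' ledger by construction.
#'
#' @param total_input SNPs entering the filter chain.
#' @param removed_call_rate SNPs removed by the call-rate rule.
#' @param removed_nonautosomal SNPs removed as nonautosomal.
#' @param removed_monomorphic_or_low_maf SNPs removed as monomorphic or
#'   low-frequency (this bin also absorbs SNPs with no calls in the
#'   comparison pair).
#' @return A `filter_ledger` object (named integer list incl. `retained`).
#' @export
#' @examples
#' filter_ledger(282587, 0, 7490, 72754)
filter_ledger <- function(total_input, removed_call_rate = 0L,
                          removed_nonautosomal = 0L,
                          removed_monomorphic_or_low_maf = 0L) {
  counts <- c(total_input = total_input,
              removed_call_rate = removed_call_rate,
              removed_nonautosomal = removed_nonautosomal,
              removed_monomorphic_or_low_maf = removed_monomorphic_or_low_maf)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("ledger counts must be non-negative integers")
  retained <- total_input - removed_call_rate - removed_nonautosomal -
    removed_monomorphic_or_low_maf
  if (retained < 0) stop("ledger removals exceed the input count")
  structure(as.list(c(counts, retained = retained)),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("SNP filter ledger\n")
  for (f in names(x))
    cat(sprintf("  %-32s %d\n", f, x[[f]]))
  invisible(x)
}

#' Convert a filter ledger to a one-row data.frame (for TSV output)
#' @param x a `filter_ledger`.
#' @param ... ignored.
#' @return One-row data.frame.
#' @export
as.data.frame.filter_ledger <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Filter SNPs by call rate
#'
#' Keeps SNPs whose fraction of non-missing calls across all individuals is
#' at least `min_rate` (boundary kept: 80/100 calls pass at 0.80).
#'
#' @param g a [genotype_matrix()].
#' @param min_rate minimum call rate in (0, 1].
#' @return list with `genotypes` (filtered matrix) and `removed` (count).
#' @export
filter_call_rate <- function(g, min_rate = 0.80) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (min_rate <= 0 || min_rate > 1) stop("min_rate must lie in (0, 1]")
  rate <- rowMeans(!is.na(g$dosage))
  keep <- rate >= min_rate
  list(genotypes = g[keep, ], removed = sum(!keep))
}

#' Filter SNPs to autosomal contigs
#'
#' @param g a [genotype_matrix()].
#' @param autosomes character set of autosomal contig names; defaults to
#'   every contig present except the sex/mitochondrial labels Z, W, X, Y,
#'   MT.
#' @return list with `genotypes` and `removed`.
#' @export
filter_autosomal <- function(g, autosomes = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  autosomes <- autosomes %||%
    setdiff(unique(g$snps$contig), c("Z", "W", "X", "Y", "MT"))
  if (length(autosomes) == 0L) stop("autosome set is empty")
  keep <- g$snps$contig %in% autosomes
  list(genotypes = g[keep, ], removed = sum(!keep))
}

#' Filter SNPs by minor allele frequency over a population pair
#'
#' The allele frequency is computed from non-missing dosages pooled over the
#' two populations of the comparison; SNPs with
#' `min(freq, 1 - freq) < min_maf` are removed. Monomorphic SNPs
#' (pooled frequency 0 or 1) and SNPs with no non-missing call in the pair
#' fall in the same removal bin. MAF exactly equal to `min_maf` is kept.
#'
#' @param g a [genotype_matrix()].
#' @param pops character vector of the two population labels compared.
#' @param min_maf minimum minor allele frequency.
#' @return list with `genotypes` and `removed`.
#' @export
filter_maf <- function(g, pops, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), length(pops) == 2L)
  if (!all(pops %in% g$population))
    stop("population(s) absent from the cohort: ",
         paste(setdiff(pops, g$population), collapse = ", "))
  cols <- g$population %in% pops
  sub <- g$dosage[, cols, drop = FALSE]
  n_called <- rowSums(!is.na(sub))
  freq <- rowSums(sub, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(freq, 1 - freq)
  keep <- n_called > 0L & !is.na(maf) & maf >= min_maf
  list(genotypes = g[keep, ], removed = sum(!keep))
}

#' Run the full SNP retention chain with ledger accounting
#'
#' Order: call rate over all individuals, then autosome restriction, then
#' pair-pooled MAF — matching the conventional accounting of a pairwise
#' differentiation screen. The retained set is order-invariant between the
#' last two steps; only the per-bin counts depend on the order.
#'
#' @param g a [genotype_matrix()].
#' @param pops the two population labels of the comparison.
#' @param min_rate minimum call rate.
#' @param autosomes autosomal contig set (see [filter_autosomal()]).
#' @param min_maf minimum pooled minor allele frequency.
#' @return list with `genotypes` (retained SNPs) and `ledger`
#'   (a [filter_ledger()]).
#' @export
filter_snps <- function(g, pops, min_rate = 0.80, autosomes = NULL,
                        min_maf = 0.05) {
  s1 <- filter_call_rate(g, min_rate)
  s2 <- filter_autosomal(s1$genotypes, autosomes)
  s3 <- filter_maf(s2$genotypes, pops, min_maf)
  ledger <- filter_ledger(
    total_input = n_snps(g),
    removed_call_rate = s1$removed,
    removed_nonautosomal = s2$removed,
    removed_monomorphic_or_low_maf = s3$removed)
  stopifnot(ledger$retained == n_snps(s3$genotypes))
  list(genotypes = s3$genotypes, ledger = ledger)
}
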