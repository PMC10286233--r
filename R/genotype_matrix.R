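#' Construct a genotype matrix
#'
#' The central container of the differentiation layer: biallelic SNP records
#' with a diploid allele-dosage matrix (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing call),
#' individual labels and a population label per individual.
#'
#' @param snps data.frame with columns `id`, `contig`, `pos` (1-based),
#'   `ref`, `alt` (single bases).
#' @param dosage integer matrix, SNPs in rows, individuals in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param individuals character vector of individual labels (column names).
#' @param population character vector, one population label per individual.
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   snps = data.frame(id = "s1", contig = "1", pos = 100L,
#'                     ref = "A", alt = "G"),
#'   dosage = matrix(c(0L, 2L), nrow = 1),
#'   individuals = c("i1", "i2"),
#'   population = c("LB", "LSL"))
#' g
genotype_matrix <- function(snps, dosage, individuals, population) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("id", "contig", "pos", "ref", "alt")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stop("snps is missing columns: ", paste(miss, collapse = ", "))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(snps))
    stop("dosage has ", nrow(dosage), " rows but snps has ", nrow(snps))
  if (ncol(dosage) != length(individuals))
    stop("dosage has ", ncol(dosage), " columns but ", length(individuals),
         " individuals were given")
  if (length(population) != length(individuals))
    stop("need one population label per individual")
  if (anyNA(population)) stop("population labels must not be NA")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be 0, 1, 2 or NA")
  if (nrow(snps)) {
    if (any(snps$pos < 1L)) stop("SNP positions must be >= 1")
    if (any(nchar(snps$ref) != 1L) || any(nchar(snps$alt) != 1L))
      stop("only biallelic single-base SNPs are allowed")
  }
  snps$pos <- as.integer(snps$pos)
  rownames(dosage) <- snps$id
  colnames(dosage) <- individuals
  structure(
    list(snps = snps, dosage = dosage,
         individuals = as.character(individuals),
         population = as.character(population)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals\n",
              n_snps(x), n_individuals(x)))
  tab <- table(x$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("contigs:", paste(sort(unique(x$snps$contig)), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of SNPs / individuals in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return Integer count.
#' @export
n_snps <- function(g) nrow(g$snps)

#' @rdname n_snps
#' @export
n_individuals <- function(g) length(g$individuals)

#' Subset a genotype matrix by SNP rows and/or individual columns
#'
#' @param x a `genotype_matrix`.
#' @param i SNP index (integer/logical).
#' @param j individual index (integer/logical) or population label(s).
#' @param ... ignored.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_snps(x))
  if (missing(j)) {
    j <- seq_len(n_individuals(x))
  } else if (is.character(j) && all(j %in% x$population)) {
    j <- which(x$population %in% j)
  }
  genotype_matrix(
    snps = x$snps[i, , drop = FALSE],
    dosage = x$dosage[i, j, drop = FALSE],
    individuals = x$individuals[j],
    population = x$population[j])
}
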