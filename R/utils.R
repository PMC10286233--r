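#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a base seed and a string key
#'
#' All randomness in the package flows from one user-visible seed. Independent
#' stages (cohort simulation, QTL simulation, ASE simulation, per-gene
#' resampling) draw from named substreams so that each stage, and each gene's
#' resampling null, is reproducible regardless of evaluation order.
#'
#' The key is hashed with a 31-ary polynomial rolling hash modulo
#' \eqn{2^{31}-1}; all intermediate values stay below \eqn{2^{53}} so the
#' arithmetic is exact in doubles and stable across platforms.
#'
#' @param seed integer base seed.
#' @param key character scalar naming the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "cohort")
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  h <- 0
  for (cd in utf8ToInt(key)) h <- (h * 31 + cd) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483645 + 1)
}

#' Convert between VCF (1-based) and BED (0-based half-open) coordinates
#'
#' The single owner of the coordinate-convention mapping: a VCF position `p`
#' corresponds to the BED point interval `[p - 1, p)`. Composing the two
#' functions is the identity, which the test suite asserts property-style.
#'
#' @param pos integer vector of 1-based VCF positions (`>= 1`).
#' @return `vcf_to_bed_pos()`: 0-based positions; `bed_to_vcf_pos()`:
#'   1-based positions.
#' @export
vcf_to_bed_pos <- function(pos) {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("VCF positions must be >= 1")
  pos - 1L
}

#' @rdname vcf_to_bed_pos
#' @param pos0 integer vector of 0-based BED positions (`>= 0`).
#' @export
bed_to_vcf_pos <- function(pos0) {
  pos0 <- as.integer(pos0)
  if (any(pos0 < 0L, na.rm = TRUE)) stop("BED positions must be >= 0")
  pos0 + 1L
}

#' Trait categories used for QTL colocalization
#'
#' The closed category set for QTL regions: egg production, egg quality,
#' fat content, growth, meat quality, feeding.
#'
#' @return Character vector of the six canonical category names.
#' @export
qtl_categories <- function() {
  c("egg production", "egg quality", "fat content", "growth",
    "meat quality", "feeding")
}

#' Normalize a QTL trait-category label
#'
#' Case-insensitive; underscores are read as spaces (BED name columns cannot
#' hold spaces). Labels outside the closed set map to `NA`.
#'
#' @param x character vector of raw labels.
#' @return Character vector of canonical categories, `NA` where unknown.
#' @export
normalize_category <- function(x) {
  y <- tolower(gsub("_", " ", trimws(as.character(x))))
  y[!y %in% qtl_categories()] <- NA_character_
  y
}

# x * log(y) with the convention 0 * log(0) = 0
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}
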