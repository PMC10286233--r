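#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' GT-only dialect: QUAL ".", FILTER "PASS", INFO ".", FORMAT "GT", genotype
#' strings "0/0", "0/1", "1/1", "./.". Rows are written in the stored SNP
#' order.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_strings <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_snps(g), n_individuals(g))
  ok <- !is.na(g$dosage)
  gt[ok] <- gt_strings[g$dosage[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s>", unique(g$snps$contig)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$individuals), collapse = "\t"))
  body <- paste(g$snps$contig, g$snps$pos, g$snps$id, g$snps$ref, g$snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Multiallelic records and indels (REF or ALT length != 1, or comma in ALT)
#' are skipped with a message giving the skip count: every downstream
#' analysis uses biallelic SNPs only. Genotypes map "0/0" to 0, "0/1"/"1/0"
#' to 1, "1/1" to 2 and "./." to missing; phased separators "|" are accepted
#' and treated as unphased.
#'
#' @param path VCF path.
#' @param populations population label per sample: either a character vector
#'   aligned with the sample columns or a named vector keyed by sample name.
#'   Defaults to a single label "unassigned".
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- methods::slot(v, "fix")
  gt <- methods::slot(v, "gt")
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample genotype columns: ", path)
  samples <- colnames(gt)[-1L]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message(n_skip, " multiallelic/indel record(s) skipped")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  # GT is the first (often only) colon-separated field
  raw <- gt[, -1L, drop = FALSE]
  raw[] <- gsub("|", "/", sub(":.*$", "", raw), fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "./." = NA_integer_, "." = NA_integer_)
  unknown <- !is.na(raw) & !(raw %in% names(code))
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1L, ]
    stop("unparseable genotype '", raw[unknown][1L], "' at record ",
         bad[["row"]], ", sample ", samples[bad[["col"]]])
  }
  dosage <- matrix(code[raw], nrow(raw), ncol(raw))

  if (is.null(populations)) {
    populations <- rep("unassigned", length(samples))
  } else if (!is.null(names(populations))) {
    miss <- setdiff(samples, names(populations))
    if (length(miss))
      stop("no population label for sample(s): ", paste(miss, collapse = ", "))
    populations <- unname(populations[samples])
  } else if (length(populations) != length(samples)) {
    stop("populations has length ", length(populations), " but the VCF has ",
         length(samples), " samples")
  }

  snps <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
  genotype_matrix(snps, dosage, samples, populations)
}
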