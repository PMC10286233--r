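#' Colocalize candidate-gene SNPs with QTL regions
#'
#' A SNP at 1-based VCF position `p` overlaps a 0-based half-open region
#' `[start, end)` iff `start <= p - 1 < end`; the coordinate conversion is
#' owned by [vcf_to_bed_pos()]. One record is emitted per (SNP, overlapping
#' region); genes with no overlapping region for any of their SNPs are
#' emitted once with category `"none"` so the non-colocalized set stays
#' visible in summaries.
#'
#' @param snps data.frame of candidate-gene SNPs: gene_id, contig, pos
#'   (1-based), optionally id.
#' @param regions data.frame of QTL regions: contig, start, end (0-based
#'   half-open), category, source_id.
#' @param comparison optional comparison label copied into each record.
#' @return data.frame: comparison, gene_id, contig, pos, source_id,
#'   category, overlap.
#' @export
overlap_snps_regions <- function(snps, regions, comparison = "all") {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  empty <- data.frame(
    comparison = character(), gene_id = character(), contig = character(),
    pos = integer(), source_id = character(), category = character(),
    overlap = logical(), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L) return(empty)

  if (nrow(regions)) {
    # [start, end) in 0-based contains p-1  <=>  1-based [start+1, end]
    # contains p
    hits <- interval_hits(snps$contig, snps$pos, snps$pos,
                          regions$contig, regions$start + 1L, regions$end)
  } else {
    hits <- data.frame(query = integer(), subject = integer())
  }
  rec <- data.frame(
    comparison = rep(comparison, nrow(hits)),
    gene_id = snps$gene_id[hits$query],
    contig = snps$contig[hits$query],
    pos = snps$pos[hits$query],
    source_id = regions$source_id[hits$subject],
    category = regions$category[hits$subject],
    overlap = rep(TRUE, nrow(hits)),
    stringsAsFactors = FALSE)

  miss <- setdiff(unique(snps$gene_id), unique(rec$gene_id))
  if (length(miss)) {
    first <- snps[match(miss, snps$gene_id), , drop = FALSE]
    rec <- rbind(rec, data.frame(
      comparison = rep(comparison, length(miss)), gene_id = first$gene_id,
      contig = first$contig, pos = first$pos,
      source_id = NA_character_, category = "none",
      overlap = FALSE, stringsAsFactors = FALSE))
  }
  rec <- rec[order(rec$gene_id, rec$contig, rec$pos, rec$category,
                   rec$source_id, na.last = TRUE), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Summarize colocalization records by trait category
#'
#' A gene counts once per category regardless of how many of its SNPs
#' overlap regions of that category; a gene overlapping regions of several
#' categories counts in each.
#'
#' @param records data.frame from [overlap_snps_regions()].
#' @return data.frame: comparison, category, n_genes — ordered by
#'   comparison then category.
#' @export
summarize_by_category <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(comparison = character(), category = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  u <- unique(records[, c("comparison", "category", "gene_id")])
  tab <- aggregate(gene_id ~ comparison + category, data = u, FUN = length)
  names(tab)[names(tab) == "gene_id"] <- "n_genes"
  tab <- tab[order(tab$comparison, tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
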