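#' Read a gene map TSV
#'
#' Expected columns: `gene_id`, `contig`, `start`, `end` with 1-based
#' inclusive coordinates. An empty file yields an empty map with a warning.
#'
#' @param path TSV path.
#' @return data.frame: gene_id, contig, start, end.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    warning("empty gene map file: ", path)
    return(empty)
  }
  gm <- read.delim(path, colClasses = "character")
  req <- c("gene_id", "contig", "start", "end")
  miss <- setdiff(req, names(gm))
  if (length(miss)) stop("gene map is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(gm) == 0L) {
    warning("gene map has a header but no rows: ", path)
    return(empty)
  }
  gm$start <- as.integer(gm$start)
  gm$end <- as.integer(gm$end)
  bad <- which(is.na(gm$start) | is.na(gm$end) | gm$start > gm$end)
  if (length(bad))
    stop("invalid gene interval at row ", bad[1L], " of ", path)
  if (anyDuplicated(gm$gene_id))
    stop("duplicated gene_id in ", path, ": ",
         gm$gene_id[duplicated(gm$gene_id)][1L])
  gm[, req]
}

#' Read QTL regions from a BED file
#'
#' Coordinates are kept 0-based half-open. The name column (column 4) holds
#' the trait category; matching is case-insensitive with underscores read as
#' spaces. Rows whose category is unknown, and rows with `start >= end`, are
#' dropped with a message.
#'
#' @param path BED path (>= 3 columns, tab-separated, no header).
#' @param categories closed set of accepted category names.
#' @return data.frame: contig, start, end, category, source_id.
#' @export
read_bed <- function(path, categories = qtl_categories()) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- read.delim(path, header = FALSE, colClasses = "character",
                    comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  contig <- bed[[1L]]
  start <- as.integer(bed[[2L]])
  end <- as.integer(bed[[3L]])
  if (anyNA(start) || anyNA(end))
    stop("non-integer BED coordinates in ", path)
  name <- if (ncol(bed) >= 4L) bed[[4L]] else rep(NA_character_, nrow(bed))

  bad_iv <- start >= end
  if (any(bad_iv))
    message(sum(bad_iv), " BED row(s) with start >= end dropped")
  cat_norm <- normalize_category(name)
  cat_norm[!cat_norm %in% categories] <- NA_character_
  bad_cat <- !bad_iv & is.na(cat_norm)
  if (any(bad_cat))
    message(sum(bad_cat), " BED row(s) with unknown category dropped")
  keep <- !bad_iv & !bad_cat
  data.frame(contig = contig[keep], start = start[keep], end = end[keep],
             category = cat_norm[keep],
             source_id = sprintf("Q%06d", which(keep)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write QTL regions as BED6
#'
#' Category names are written with underscores in the name column; score 0,
#' strand ".".
#'
#' @param regions data.frame: contig, start, end, category (and optionally
#'   source_id, ignored on write).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  lines <- paste(regions$contig, regions$start, regions$end,
                 gsub(" ", "_", regions$category), 0L, ".", sep = "\t")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an allelic read-count table
#'
#' Expected columns: individual, strain, week, gene_id, contig, pos,
#' ref_reads, alt_reads. Negative read counts are rejected with the row
#' number.
#'
#' @param path TSV path.
#' @return data.frame with the columns above.
#' @export
read_ase_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("individual", "strain", "week", "gene_id", "contig", "pos",
           "ref_reads", "alt_reads")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("ASE count table is missing columns: ",
                         paste(miss, collapse = ", "))
  x$contig <- as.character(x$contig)
  for (col in c("pos", "ref_reads", "alt_reads"))
    x[[col]] <- as.integer(x[[col]])
  bad <- which(is.na(x$ref_reads) | is.na(x$alt_reads) |
                 x$ref_reads < 0L | x$alt_reads < 0L)
  if (length(bad))
    stop("invalid read counts at row ", bad[1L], " of ", path)
  x[, req]
}

#' Write a results table as deterministic TSV
#'
#' Header line, tab separated, UTF-8, no quoting, no row names. If
#' `sort_by` names columns, rows are ordered by them so repeated runs give
#' byte-identical files.
#'
#' @param records data.frame.
#' @param path output path.
#' @param sort_by character vector of column names to sort rows by.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort_by = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.null(sort_by) && nrow(records)) {
    miss <- setdiff(sort_by, names(records))
    if (length(miss)) stop("sort_by column(s) not present: ",
                           paste(miss, collapse = ", "))
    records <- records[do.call(order, records[sort_by]), , drop = FALSE]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "", eol = "\n")
  invisible(path)
}

#' Write a gene map TSV
#' @param gene_map data.frame: gene_id, contig, start, end.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_map, path) {
  write_table(gene_map[, c("gene_id", "contig", "start", "end")], path)
}
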