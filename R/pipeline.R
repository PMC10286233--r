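#' Build a validated pipeline run configuration
#'
#' A run uses exactly one input source: either `simulation` (blocks for the
#' cohort, the QTL regions and the ASE counts, passed to the generators) or
#' `inputs` (paths: vcf, populations, gene_map, qtl_bed, ase_counts).
#'
#' @param seed integer base seed; stage substreams are derived from it.
#' @param out_dir output directory.
#' @param comparisons list of 2-vectors of population labels.
#' @param simulation list with elements `cohort`, `qtl`, `ase` (argument
#'   lists for [cohort_sim_config()], [simulate_qtl_regions()] and
#'   [ase_sim_config()]), or `NULL`.
#' @param inputs named list of file paths, or `NULL`.
#' @param thresholds named list overriding any of: min_rate, min_maf,
#'   min_snps, z_threshold, top_fraction, min_minor_count, min_total,
#'   min_minor_ratio, R_max, batch, stop_hits, alpha, fdr_level.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "fstase_out",
                       comparisons = list(c("LB", "LSL")),
                       simulation = NULL, inputs = NULL,
                       thresholds = list()) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of simulation or inputs must be given")
  defaults <- list(min_rate = 0.80, min_maf = 0.05, min_snps = 3L,
                   z_threshold = 4, top_fraction = 0.01,
                   min_minor_count = 3L, min_total = 30L,
                   min_minor_ratio = 0.01, R_max = 10000L, batch = 1000L,
                   stop_hits = 50L, alpha = 0.05, fdr_level = 0.05)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stop("unknown threshold(s): ",
                            paste(unknown, collapse = ", "))
  th <- utils::modifyList(defaults, thresholds)
  if (th$min_rate <= 0 || th$min_rate > 1) stop("min_rate out of range")
  if (th$min_maf < 0 || th$min_maf >= 0.5) stop("min_maf out of range")
  if (th$top_fraction <= 0 || th$top_fraction > 1)
    stop("top_fraction out of range")
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha out of range")
  if (th$R_max < th$batch) stop("R_max must be >= batch")
  comparisons <- lapply(comparisons, as.character)
  if (any(vapply(comparisons, length, 1L) != 2L))
    stop("each comparison must name exactly two populations")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 comparisons = comparisons, simulation = simulation,
                 inputs = inputs, thresholds = th),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `write_run_config()` serializes the configuration; `read_run_config()`
#' parses and re-validates it. Serialize-parse-serialize is the identity on
#' the YAML text.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()`: a `run_config`; `write_run_config()`:
#'   `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- yaml::read_yaml(path)
  run_config(seed = x$seed, out_dir = x$out_dir,
             comparisons = x$comparisons, simulation = x$simulation,
             inputs = x$inputs, thresholds = x$thresholds %||% list())
}

#' Run the differentiation workflow for every configured comparison
#'
#' Per comparison: SNP filtering with ledger accounting, the gene-level
#' FST scan, and QTL colocalization of the candidate genes' SNPs. All
#' tables are written as deterministic TSV under `out_dir`, together with a
#' machine-readable JSON manifest of thresholds, seed and counts.
#'
#' @param genotypes a [genotype_matrix()].
#' @param gene_map data.frame: gene_id, contig, start, end.
#' @param regions QTL region data.frame (see [read_bed()]).
#' @param comparisons list of 2-vectors of population labels.
#' @param thresholds threshold list as held in a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param seed seed recorded in the manifest.
#' @return Named list per comparison: `ledger`, `genes`, `coloc`,
#'   `coloc_summary`, `mu`, `sigma`; plus `manifest`.
#' @export
run_fst_workflow <- function(genotypes, gene_map, regions, comparisons,
                             thresholds, out_dir = NULL, seed = NA_integer_) {
  th <- thresholds
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- list()
  manifest <- list(seed = seed, thresholds = th,
                   n_snps_input = n_snps(genotypes),
                   comparisons = list())
  for (cmp in comparisons) {
    label <- paste(cmp, collapse = "_vs_")
    flt <- tryCatch(
      filter_snps(genotypes, cmp, min_rate = th$min_rate,
                  min_maf = th$min_maf),
      error = function(e) stop("snp_filter [", label, "]: ",
                               conditionMessage(e), call. = FALSE))
    scan <- tryCatch(
      gene_fst_scan(flt$genotypes, cmp, gene_map,
                    min_snps = th$min_snps, z_threshold = th$z_threshold,
                    top_fraction = th$top_fraction),
      error = function(e) stop("fst_scan [", label, "]: ",
                               conditionMessage(e), call. = FALSE))

    cand <- scan$genes$gene_id[scan$genes$is_candidate]
    cand_snp_rows <- merge(
      scan$per_snp[!is.na(scan$per_snp$theta),
                   c("id", "contig", "pos")],
      gene_snp_assignment(scan$per_snp, gene_map, cand),
      by = "id")
    coloc <- tryCatch(
      overlap_snps_regions(cand_snp_rows, regions, comparison = label),
      error = function(e) stop("qtl_coloc [", label, "]: ",
                               conditionMessage(e), call. = FALSE))
    csum <- summarize_by_category(coloc)

    message(sprintf(
      "[%s] input %d SNPs -> retained %d; %d genes tested; %d candidates",
      label, flt$ledger$total_input, flt$ledger$retained,
      nrow(scan$genes), length(cand)))

    out[[label]] <- list(ledger = flt$ledger, genes = scan$genes,
                         coloc = coloc, coloc_summary = csum,
                         mu = scan$mu, sigma = scan$sigma)
    manifest$comparisons[[label]] <- list(
      ledger = unclass(flt$ledger), n_genes = nrow(scan$genes),
      n_candidates = length(cand),
      n_top_fraction = sum(scan$genes$in_top_fraction),
      mu_fst = scan$mu, sigma_fst = scan$sigma)

    if (!is.null(out_dir)) {
      write_table(as.data.frame(flt$ledger),
                  file.path(out_dir, paste0(label, "_ledger.tsv")))
      write_table(scan$genes,
                  file.path(out_dir, paste0(label, "_gene_fst.tsv")),
                  sort_by = "gene_id")
      write_table(coloc, file.path(out_dir, paste0(label, "_coloc.tsv")))
      write_table(csum,
                  file.path(out_dir, paste0(label, "_coloc_summary.tsv")))
    }
  }
  out$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "fst_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

# SNP -> gene assignment restricted to a gene subset; returns
# data.frame(id, gene_id), one row per (SNP, containing gene).
gene_snp_assignment <- function(per_snp, gene_map, gene_subset = NULL) {
  gm <- gene_map
  if (!is.null(gene_subset))
    gm <- gm[gm$gene_id %in% gene_subset, , drop = FALSE]
  snp <- per_snp[!is.na(per_snp$theta), , drop = FALSE]
  if (nrow(gm) == 0L || nrow(snp) == 0L)
    return(data.frame(id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  hits <- interval_hits(snp$contig, snp$pos, snp$pos,
                        gm$contig, gm$start, gm$end)
  data.frame(id = snp$id[hits$query], gene_id = gm$gene_id[hits$subject],
             stringsAsFactors = FALSE)
}

#' Classify gene membership across strain-by-week ASE results
#'
#' From the gene-by-group significance flags (`p_empirical < alpha`)
#' derives, per gene:
#' * `specific(s, w)` — significant in strain `s` at week `w` and not
#'   significant in the other strain at the same week;
#' * `common_across_weeks(s)` — significant in strain `s` at every week;
#' * `common_both` — significant in both strains at every week.
#'
#' Requires a complete strain-by-week grid of results (two strains).
#'
#' @param ase_results data.frame from [ase_scan()].
#' @param alpha significance threshold on the empirical p-value.
#' @return list of class `membership_table`: `flags` and `specific`
#'   (gene-by-group logical matrices with "strain_week" columns),
#'   `common_across_weeks` (gene-by-strain logical matrix), `common_both`
#'   (named logical), `strains`, `weeks`.
#' @export
classify_membership <- function(ase_results, alpha = 0.05) {
  strains <- sort(unique(ase_results$strain))
  weeks <- sort(unique(ase_results$week))
  if (length(strains) != 2L)
    stop("membership classification needs exactly two strains, got: ",
         paste(strains, collapse = ", "))
  have <- unique(paste(ase_results$strain, ase_results$week))
  need <- as.vector(outer(strains, weeks, paste))
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing ASE results for group(s): ", paste(miss, collapse = "; "))

  genes <- sort(unique(ase_results$gene_id))
  cols <- as.vector(t(outer(strains, weeks, paste, sep = "_")))
  flags <- matrix(FALSE, length(genes), length(cols),
                  dimnames = list(genes, cols))
  sig <- ase_results$p_empirical < alpha
  idx <- cbind(match(ase_results$gene_id, genes),
               match(paste(ase_results$strain, ase_results$week, sep = "_"),
                     cols))
  flags[idx] <- sig

  specific <- flags
  for (w in weeks) {
    c1 <- paste(strains[1L], w, sep = "_")
    c2 <- paste(strains[2L], w, sep = "_")
    specific[, c1] <- flags[, c1] & !flags[, c2]
    specific[, c2] <- flags[, c2] & !flags[, c1]
  }
  common <- vapply(strains, function(s)
    rowSums(flags[, paste(s, weeks, sep = "_"), drop = FALSE]) ==
      length(weeks), logical(length(genes)))
  structure(list(flags = flags, specific = specific,
                 common_across_weeks = common,
                 common_both = common[, 1L] & common[, 2L],
                 strains = strains, weeks = weeks),
            class = "membership_table")
}

#' Strain-specific ASE accounting in the row-sum convention
#'
#' Per strain and week: the number of ASE genes and the number of
#' strain-specific ASE genes. The per-strain `specific_total` is the sum of
#' the five per-week specific counts (genes recurring across weeks count
#' each time — the row-sum convention of a per-week table); the distinct
#' gene count is reported alongside as `specific_distinct`.
#'
#' @param membership a [classify_membership()] result.
#' @return list: `per_week` (data.frame: strain, week, n_ase, n_specific),
#'   `totals` (data.frame: strain, specific_total, specific_distinct,
#'   common_across_weeks), `common_both` (count).
#' @export
membership_summary <- function(membership) {
  stopifnot(inherits(membership, "membership_table"))
  st <- membership$strains
  wk <- membership$weeks
  per_week <- do.call(rbind, lapply(st, function(s) {
    data.frame(
      strain = s, week = wk,
      n_ase = colSums(membership$flags[, paste(s, wk, sep = "_"),
                                       drop = FALSE]),
      n_specific = colSums(membership$specific[, paste(s, wk, sep = "_"),
                                               drop = FALSE]),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  totals <- do.call(rbind, lapply(st, function(s) {
    spec <- membership$specific[, paste(s, wk, sep = "_"), drop = FALSE]
    total <- sum(colSums(spec))
    stopifnot(total == sum(per_week$n_specific[per_week$strain == s]))
    data.frame(strain = s,
               specific_total = total,
               specific_distinct = sum(rowSums(spec) > 0),
               common_across_weeks = sum(membership$common_across_weeks[, s]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(per_week = per_week, totals = totals,
       common_both = sum(membership$common_both))
}

#' Overlap strain-specific ASE genes with the top-fraction FST gene set
#'
#' Per (strain, week): the count of strain-specific ASE genes that also sit
#' in the top Z(FST) fraction, reported alongside the specific count as a
#' "k/n" label.
#'
#' @param membership a [classify_membership()] result.
#' @param top_genes character vector of top-fraction gene ids.
#' @return data.frame: strain, week, n_specific, n_overlap, ratio.
#' @export
fst_ase_overlap <- function(membership, top_genes) {
  stopifnot(inherits(membership, "membership_table"))
  genes <- rownames(membership$specific)
  out <- do.call(rbind, lapply(membership$strains, function(s) {
    do.call(rbind, lapply(membership$weeks, function(w) {
      spec <- genes[membership$specific[, paste(s, w, sep = "_")]]
      k <- length(intersect(spec, top_genes))
      data.frame(strain = s, week = w, n_specific = length(spec),
                 n_overlap = k,
                 ratio = sprintf("%d/%d", k, length(spec)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Run the complete two-layer pipeline from one configuration
#'
#' With a `simulation` block: generates the cohort, QTL regions and ASE
#' counts from named substreams of the base seed, round-trips the genotypes
#' through VCF and the regions through BED, then runs the differentiation
#' workflow per comparison and the ASE workflow per (strain, week) group,
#' classifies membership, and intersects strain-specific ASE genes with the
#' top Z(FST) fraction of the first comparison. With an `inputs` block the
#' same analyses run on files read from disk.
#'
#' Every output table is deterministic TSV; one seed reproduces the output
#' tree byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisible list: `fst` (per-comparison results), `ase`
#'   (ase_scan table), `membership`, `summary`, `overlap`, `truth` (when
#'   simulated).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- NULL

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    cohort_cfg <- do.call(cohort_sim_config, utils::modifyList(
      sim$cohort %||% list(),
      list(seed = substream_seed(config$seed, "cohort"))))
    cohort <- simulate_cohort(cohort_cfg)

    vcf_path <- file.path(out_dir, "cohort.vcf")
    write_vcf(cohort$genotypes, vcf_path)
    genotypes <- read_vcf(vcf_path, stats::setNames(
      cohort$genotypes$population, cohort$genotypes$individuals))
    gene_map <- cohort$gene_map
    write_gene_map(gene_map, file.path(out_dir, "gene_map.tsv"))

    layout <- tapply(
      pmax(genotypes$snps$pos, 1L) + 10000L, genotypes$snps$contig, max)
    qtl_args <- utils::modifyList(list(n_regions = 50L), sim$qtl %||% list())
    qtl_args$genome_layout <- c(layout)
    qtl_args$seed <- substream_seed(config$seed, "qtl")
    regions <- do.call(simulate_qtl_regions, qtl_args)
    bed_path <- file.path(out_dir, "qtl.bed")
    write_bed(regions, bed_path)
    regions <- read_bed(bed_path)

    ase_cfg <- do.call(ase_sim_config, utils::modifyList(
      sim$ase %||% list(),
      list(seed = substream_seed(config$seed, "ase"))))
    ase_sim <- simulate_ase_counts(gene_map, ase_cfg)
    write_table(ase_sim$counts, file.path(out_dir, "ase_counts.tsv"))
    ase_counts <- ase_sim$counts
    truth <- list(cohort = cohort$truth, ase = ase_sim$truth)
  } else {
    ins <- config$inputs
    pops <- NULL
    if (!is.null(ins$populations)) {
      pt <- read.delim(ins$populations, stringsAsFactors = FALSE)
      pops <- stats::setNames(pt$population, pt$individual)
    }
    genotypes <- read_vcf(ins$vcf, pops)
    gene_map <- read_gene_map(ins$gene_map)
    regions <- read_bed(ins$qtl_bed)
    ase_counts <- read_ase_counts(ins$ase_counts)
  }

  fst <- run_fst_workflow(genotypes, gene_map, regions, config$comparisons,
                          th, out_dir = out_dir, seed = config$seed)

  rule <- ase_filter_rule(th$min_minor_count, th$min_total,
                          th$min_minor_ratio)
  ase <- ase_scan(ase_counts, rule = rule, R_max = th$R_max,
                  batch = th$batch, stop_hits = th$stop_hits,
                  seed = config$seed, fdr_level = th$fdr_level)
  write_table(ase, file.path(out_dir, "ase_results.tsv"),
              sort_by = c("strain", "week", "gene_id"))

  membership <- classify_membership(ase, alpha = th$alpha)
  msum <- membership_summary(membership)
  write_table(msum$per_week, file.path(out_dir, "ase_membership.tsv"))
  write_table(msum$totals, file.path(out_dir, "ase_totals.tsv"))

  first <- paste(config$comparisons[[1L]], collapse = "_vs_")
  top1 <- fst[[first]]$genes$gene_id[fst[[first]]$genes$in_top_fraction]
  overlap <- fst_ase_overlap(membership, top1)
  write_table(overlap, file.path(out_dir, "fst_ase_overlap.tsv"))

  manifest <- list(
    seed = config$seed, thresholds = th,
    comparisons = lapply(config$comparisons, paste, collapse = "_vs_"),
    n_ase_tests = nrow(ase),
    n_ase_skipped = nrow(attr(ase, "skipped")),
    specific_totals = stats::setNames(as.list(msum$totals$specific_total),
                                      msum$totals$strain),
    common_both = msum$common_both)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(fst = fst, ase = ase, membership = membership,
                 summary = msum, overlap = overlap, truth = truth))
}
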