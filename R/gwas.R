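#' Construct SNP and gene coordinate tables
#'
#' `snp_records()` carries GWAS SNPs as (snp_id, chrom, pos) with 1-based
#' positions; `gene_intervals()` carries gene bodies as
#' (gene_id, chrom, start, end), 1-based inclusive.
#'
#' @param snp_id,gene_id,chrom Character vectors.
#' @param pos,start,end Integer coordinates; `pos >= 1`, `start <= end`.
#' @return A validated tibble.
#' @export
snp_records <- function(snp_id, chrom, pos) {
  tbl <- tibble::tibble(snp_id = as.character(snp_id),
                        chrom = as.character(chrom),
                        pos = as.numeric(pos))
  if (any(tbl$pos < 1)) stop("SNP positions must be >= 1", call. = FALSE)
  tbl
}

#' @rdname snp_records
#' @export
gene_intervals <- function(gene_id, chrom, start, end) {
  tbl <- tibble::tibble(gene_id = as.character(gene_id),
                        chrom = as.character(chrom),
                        start = as.numeric(start), end = as.numeric(end))
  if (any(tbl$start > tbl$end)) {
    stop("gene intervals must satisfy start <= end", call. = FALSE)
  }
  if (any(tbl$start < 1)) stop("coordinates must be >= 1", call. = FALSE)
  tbl
}

#' Read SNPs or gene intervals from BED-like files
#'
#' BED coordinates are 0-based half-open; they are converted to the
#' 1-based inclusive convention used internally. SNP files are 4-column
#' (chrom, pos0, pos0 + 1, snp_id); gene files are 4-column
#' (chrom, start0, end0, gene_id). Headerless, tab-delimited.
#'
#' @param path Path to the BED-like file.
#' @return A [snp_records()] or [gene_intervals()] tibble.
#' @export
read_snp_bed <- function(path) {
  raw <- read_bed4(path)
  snp_records(snp_id = raw[[4]], chrom = raw[[1]], pos = raw[[2]] + 1)
}

#' @rdname read_snp_bed
#' @export
read_gene_bed <- function(path) {
  raw <- read_bed4(path)
  gene_intervals(gene_id = raw[[4]], chrom = raw[[1]],
                 start = raw[[2]] + 1, end = raw[[3]])
}

read_bed4 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 4) stop("expected at least 4 BED columns", call. = FALSE)
  raw[[2]] <- as.numeric(raw[[2]]); raw[[3]] <- as.numeric(raw[[3]])
  raw
}

#' Positional candidate genes around GWAS SNPs
#'
#' A gene is a positional candidate for a SNP when its body overlaps a
#' window of `window_bp` base pairs centered on the SNP position
#' (inclusive interval overlap on the same chromosome). The default 20 kb
#' window favors specificity: it contains the most likely candidates at
#' the cost of missing distal ones. With `window_bp = 0` only genes whose
#' body contains the SNP qualify.
#'
#' @param snps A [snp_records()] tibble.
#' @param genes A [gene_intervals()] tibble.
#' @param window_bp Window width in base pairs (default 20000).
#' @return A tibble (`snp_id`, `gene_id`), one row per qualifying pair;
#'   SNPs with no candidate contribute no rows.
#' @export
positional_candidates <- function(snps, genes, window_bp = 20000) {
  stopifnot(window_bp >= 0)
  half <- window_bp / 2
  dplyr::inner_join(snps, genes, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$pos + half,
                  .data$end >= .data$pos - half) |>
    dplyr::distinct(.data$snp_id, .data$gene_id) |>
    dplyr::arrange(.data$snp_id, .data$gene_id)
}

#' Phase 1: detect priority cell types by positional-candidate enrichment
#'
#' For each cell type, tests whether the GWAS positional candidates are
#' enriched in its top `top_n` predicted genes (one-sided Fisher's exact
#' test on the shared gene universe), then adjusts across cell types with
#' Holm's method. Cell types with adjusted p at or below `alpha` are
#' flagged as data-driven priority cell types. (Literature-derived
#' priority cell types can be added downstream; see [prioritize_gwas()].)
#'
#' @param predictions Named list of ranked gene identifier vectors (best
#'   first), one per cell type; or a tibble with columns `cell_type`,
#'   `gene_id` ordered by rank within cell type.
#' @param gwas_candidates Character vector of positional candidate genes.
#' @param universe Character vector: the gene background.
#' @param top_n Prediction-list depth tested (default 200).
#' @param alpha Holm-adjusted significance cutoff (default 0.05).
#' @return A tibble (`cell_type`, `n_overlap`, `n_top`, `odds_ratio`,
#'   `p_value`, `p_holm`, `priority`), ordered by `p_holm`.
#' @export
phase1_priority_cell_types <- function(predictions, gwas_candidates,
                                       universe, top_n = 200,
                                       alpha = 0.05) {
  if (is.data.frame(predictions)) {
    predictions <- split(predictions$gene_id, predictions$cell_type)
  }
  stopifnot(is.list(predictions), length(predictions) > 0,
            !is.null(names(predictions)))
  gwas_candidates <- unique(as.character(gwas_candidates))
  if (length(gwas_candidates) == 0) {
    stop("GWAS candidate set is empty", call. = FALSE)
  }
  short <- names(predictions)[lengths(predictions) < top_n]
  if (length(short) > 0) {
    stop("prediction list(s) shorter than top_n = ", top_n, ": ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  res <- purrr::imap_dfr(predictions, function(ranked, ct) {
    top <- utils::head(ranked, top_n)
    fisher <- enrichment_fisher(top, gwas_candidates, universe)
    tibble::tibble(cell_type = ct, n_overlap = fisher$n_overlap,
                   n_top = length(top), odds_ratio = fisher$odds_ratio,
                   p_value = fisher$p_value)
  })
  res$p_holm <- adjust_holm(pmax(res$p_value, .Machine$double.xmin))
  res$priority <- res$p_holm <= alpha
  dplyr::arrange(res, .data$p_holm, .data$cell_type)
}

#' Phase 2: select in-locus genes predicted for priority cell types
#'
#' Emits every (SNP, gene, cell type) triple where the gene body lies
#' within `max_distance_bp` of the SNP (nearest-edge distance, 0 when the
#' SNP falls inside the gene, boundary inclusive) and the gene's pooled
#' FDR for that priority cell type is at or below `fdr_threshold`. This
#' phase favors sensitivity: the 250 kb default approximates the reach of
#' linkage disequilibrium by distance alone, and the lenient FDR of 0.1
#' keeps plausible candidates.
#'
#' @param snps A [snp_records()] tibble.
#' @param genes A [gene_intervals()] tibble.
#' @param pooled Named list (cell type -> pooled result tibble with
#'   columns `gene_id` and `combined_fdr` or `fdr`), one entry per
#'   priority cell type.
#' @param max_distance_bp Maximum SNP-to-gene distance (default 250000).
#' @param fdr_threshold Pooled FDR cutoff (default 0.1).
#' @return A tibble (`snp_id`, `gene_id`, `cell_type`, `fdr`,
#'   `distance_bp`), ordered by (`snp_id`, `fdr`).
#' @export
phase2_select_candidates <- function(snps, genes, pooled,
                                     max_distance_bp = 250000,
                                     fdr_threshold = 0.1) {
  stopifnot(is.list(pooled))
  if (length(pooled) == 0) {
    stop("no priority cell types supplied", call. = FALSE)
  }
  stopifnot(!is.null(names(pooled)))
  near <- dplyr::inner_join(snps, genes, by = "chrom",
                            relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = dplyr::if_else(
      .data$pos >= .data$start & .data$pos <= .data$end, 0,
      pmin(abs(.data$pos - .data$start), abs(.data$pos - .data$end))
    )) |>
    dplyr::filter(.data$distance_bp <= max_distance_bp) |>
    dplyr::select("snp_id", "gene_id", "distance_bp")
  hits <- purrr::imap_dfr(pooled, function(tbl, ct) {
    fdr_col <- if ("combined_fdr" %in% colnames(tbl)) "combined_fdr"
               else "fdr"
    stopifnot(fdr_col %in% colnames(tbl), "gene_id" %in% colnames(tbl))
    keep <- tbl[tbl[[fdr_col]] <= fdr_threshold, ]
    tibble::tibble(gene_id = keep$gene_id, cell_type = ct,
                   fdr = keep[[fdr_col]])
  })
  dplyr::inner_join(near, hits, by = "gene_id",
                    relationship = "many-to-many") |>
    dplyr::select("snp_id", "gene_id", "cell_type", "fdr",
                  "distance_bp") |>
    dplyr::arrange(.data$snp_id, .data$fdr, .data$gene_id)
}

#' Two-phase GWAS candidate-gene prioritization
#'
#' Phase 1 scans all cell types for enrichment of positional candidates
#' (20 kb windows) among their top predictions and flags the Holm-passing
#' ones as priority cell types; any `extra_priority` cell types supplied
#' from the literature are added. Phase 2 then selects every gene within
#' 250 kb of a GWAS SNP that is predicted for a priority cell type at a
#' pooled FDR of at most `fdr_threshold`.
#'
#' @inheritParams phase1_priority_cell_types
#' @inheritParams phase2_select_candidates
#' @param extra_priority Cell types to treat as priority regardless of the
#'   enrichment test (the literature-review arm).
#' @param window_bp Phase-1 candidate window (default 20000).
#' @return An object of class `gwas_prioritization`: list with
#'   `candidates` (phase-1 positional candidates), `phase1` (enrichment
#'   table), `priority_cell_types`, and `selected` (phase-2 table).
#' @export
prioritize_gwas <- function(snps, genes, predictions, pooled, universe,
                            window_bp = 20000, top_n = 200, alpha = 0.05,
                            max_distance_bp = 250000, fdr_threshold = 0.1,
                            extra_priority = character()) {
  cands <- positional_candidates(snps, genes, window_bp = window_bp)
  cand_genes <- intersect(unique(cands$gene_id), universe)
  phase1 <- phase1_priority_cell_types(predictions, cand_genes, universe,
                                       top_n = top_n, alpha = alpha)
  priority <- union(phase1$cell_type[phase1$priority], extra_priority)
  selected <- if (length(priority) > 0) {
    phase2_select_candidates(snps, genes, pooled[priority],
                             max_distance_bp = max_distance_bp,
                             fdr_threshold = fdr_threshold)
  } else {
    tibble::tibble(snp_id = character(), gene_id = character(),
                   cell_type = character(), fdr = numeric(),
                   distance_bp = numeric())
  }
  structure(list(candidates = cands, phase1 = phase1,
                 priority_cell_types = priority, selected = selected),
            class = "gwas_prioritization")
}

#' @export
print.gwas_prioritization <- function(x, ...) {
  cat("<gwas_prioritization> ", length(x$priority_cell_types),
      " priority cell type(s): ",
      paste(x$priority_cell_types, collapse = ", "), "\n",
      nrow(x$selected), " prioritized (SNP, gene, cell type) triple(s)\n",
      sep = "")
  invisible(x)
}
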