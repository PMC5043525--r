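#' Tidy a marker_search result
#'
#' Returns the pooled per-gene table: one row per scored gene with the
#' Stouffer-combined z, one-sided p, BH FDR, rank and predicted flag.
#'
#' @param x A [marker_search()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.marker_search <- function(x, ...) {
  x$pooled
}

#' Summarize a marker_search result in one row
#'
#' @param x A [marker_search()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_platforms`, `n_predicted`,
#'   `fdr_threshold`, `alpha`, `use_filter`.
#' @export
glance.marker_search <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$pooled),
    n_platforms = length(x$platforms),
    n_predicted = sum(x$pooled$predicted),
    fdr_threshold = x$params$fdr_threshold,
    alpha = x$params$alpha,
    use_filter = x$params$use_filter
  )
}

#' Tidy a gwas_prioritization result
#'
#' @param x A [prioritize_gwas()] object.
#' @param ... Unused.
#' @return The phase-2 table of prioritized (SNP, gene, cell type)
#'   triples.
#' @export
tidy.gwas_prioritization <- function(x, ...) {
  x$selected
}

#' @rdname glance.marker_search
#' @export
glance.gwas_prioritization <- function(x, ...) {
  tibble::tibble(
    n_candidates = dplyr::n_distinct(x$candidates$gene_id),
    n_cell_types_tested = nrow(x$phase1),
    n_priority = length(x$priority_cell_types),
    n_selected = nrow(x$selected)
  )
}
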