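#' Mean Fisher-transformed correlation with the query genes
#'
#' For each gene g, computes the Pearson correlation of its (filtered)
#' profile with each query gene's profile across samples, applies the
#' variance-stabilizing Fisher transformation atanh(rho) =
#' (1/2) ln((1 + rho)/(1 - rho)), and averages over the N query genes.
#' Correlations are clamped to +/-(1 - 1e-12) before the transform so that
#' perfectly correlated duplicates stay finite. Query genes themselves are
#' excluded from the output (their self-correlation of 1 is uninformative);
#' genes whose filtered profile has zero variance get a neutral zbar of 0
#' and are flagged, so the output covers the full non-query gene universe.
#'
#' @param filtered Gene-by-sample matrix (typically from [svd_filter()]).
#' @param query Query gene identifiers or row indices.
#' @return A tibble with columns `gene_id`, `zbar`, `zero_variance`.
#' @examples
#' x <- simulate_null(50, 20, seed = 3)
#' mean_fisher_correlation(x, rownames(x)[1])
#' @export
mean_fisher_correlation <- function(filtered, query) {
  stopifnot(is.matrix(filtered))
  if (ncol(filtered) < 3) {
    stop("at least 3 samples required for correlation", call. = FALSE)
  }
  ids <- rownames(filtered) %||% as.character(seq_len(nrow(filtered)))
  if (is.character(query)) {
    qrows <- match(query, ids)
    if (anyNA(qrows)) {
      stop("query gene(s) not present in matrix: ",
           paste(query[is.na(qrows)], collapse = ", "), call. = FALSE)
    }
  } else {
    qrows <- as.integer(query)
  }
  sds <- apply(filtered, 1, stats::sd)
  rho <- suppressWarnings(
    stats::cor(t(filtered), t(filtered[qrows, , drop = FALSE]))
  )
  rho[!is.finite(rho)] <- 0           # zero-variance profiles: neutral
  rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  zbar <- rowMeans(atanh(rho))
  flat <- sds < 1e-12
  zbar[flat] <- 0
  keep <- setdiff(seq_len(nrow(filtered)), qrows)
  tibble::tibble(gene_id = ids[keep], zbar = unname(zbar[keep]),
                 zero_variance = unname(flat[keep]))
}

#' Robust z-scores by median/MAD standardization
#'
#' Standardizes a vector of mean Fisher-z scores against its own bulk:
#' S_g = (zbar_g - median(z)) / (1.4826 * MAD(z)), with MAD the unscaled
#' median absolute deviation from the median. The 1.4826 factor makes the
#' MAD estimate a normal standard deviation, so under the null S_g is
#' approximately standard normal while remaining insensitive to the heavy
#' upper tail the true positives create.
#'
#' @param zbar Numeric vector of length >= 3.
#' @return Numeric vector of robust z-scores.
#' @examples
#' robust_standardize(c(1, 2, 3, 4, 100))
#' @export
robust_standardize <- function(zbar) {
  if (length(zbar) < 3) {
    stop("at least 3 values required for robust standardization",
         call. = FALSE)
  }
  med <- stats::median(zbar)
  mad_raw <- stats::median(abs(zbar - med))
  if (mad_raw <= 0) {
    stop("degenerate score distribution: MAD is zero", call. = FALSE)
  }
  (zbar - med) / (1.4826 * mad_raw)
}

#' One-sided p-values from standard-normal scores
#'
#' Upper-tail standard-normal probability: large positive scores indicate
#' enrichment, which is the only direction of interest. Values are floored
#' at the smallest positive double so downstream log/quantile operations
#' stay finite.
#'
#' @param s Numeric vector of z-scores.
#' @return Numeric vector of p-values in (0, 1\].
#' @export
scores_to_pvalues <- function(s) {
  pmax(stats::pnorm(s, lower.tail = FALSE), .Machine$double.xmin)
}

#' Benjamini-Hochberg and Holm multiple-testing adjustment
#'
#' `adjust_bh()` controls the false discovery rate (step-up), used when the
#' goal is a candidate list that tolerates a small fraction of false
#' positives; `adjust_holm()` controls the family-wise error rate
#' (step-down), used when individual test results are interpreted
#' directly.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, monotone and capped at 1.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' adjust_holm(c(0.01, 0.04))
#' @export
adjust_bh <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_holm <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "holm")
}

check_pvalues <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p <= 0) || any(p > 1))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Stouffer pooling of per-platform z-scores
#'
#' Combines one-sided evidence for each gene across platforms by summing
#' the per-platform normal quantiles and dividing by the square root of the
#' number of platforms on which the gene is present:
#' Z = sum(z_i) / sqrt(k). Genes measured on fewer platforms simply use
#' fewer terms. k identical scores z combine to z * sqrt(k).
#'
#' @param z_by_platform Either a tibble with columns `gene_id`, `platform`,
#'   `z`, or a named list of per-platform tibbles with columns `gene_id`
#'   and `z` (extra columns ignored).
#' @return A tibble with columns `gene_id`, `combined_z`, `combined_p`,
#'   `combined_fdr`, `n_platforms`, ordered by (`combined_p`, `gene_id`).
#' @examples
#' stouffer_pool(tibble::tibble(gene_id = c("g1", "g1"),
#'                              platform = c("a", "b"),
#'                              z = c(1.644854, 1.644854)))
#' @export
stouffer_pool <- function(z_by_platform) {
  if (is.data.frame(z_by_platform)) {
    tbl <- z_by_platform
  } else {
    stopifnot(is.list(z_by_platform), length(z_by_platform) > 0)
    nm <- names(z_by_platform) %||% paste0("platform_", seq_along(z_by_platform))
    tbl <- purrr::map2_dfr(z_by_platform, nm, function(d, n) {
      tibble::tibble(gene_id = d$gene_id, platform = n, z = d$z)
    })
  }
  stopifnot(all(c("gene_id", "z") %in% colnames(tbl)))
  if (nrow(tbl) == 0) stop("no scores to pool", call. = FALSE)
  pooled <- tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      combined_z = sum(.data$z) / sqrt(dplyr::n()),
      n_platforms = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      combined_p = scores_to_pvalues(.data$combined_z),
      combined_fdr = adjust_bh(.data$combined_p)
    ) |>
    dplyr::arrange(.data$combined_p, .data$gene_id) |>
    dplyr::select("gene_id", "combined_z", "combined_p", "combined_fdr",
                  "n_platforms")
  pooled
}

#' Score one platform against the query genes
#'
#' Runs the single-platform pipeline: gene standardization, SVD
#' factorization, Kaiser truncation, query-adaptive filtering, mean
#' Fisher-z correlation, robust standardization, and one-sided normal
#' p-values with BH adjustment. Setting `use_filter = FALSE` bypasses the
#' SVD filter and correlates on the standardized matrix directly — the
#' baseline against which the filter's benefit is measured.
#'
#' @inheritParams svd_filter
#' @param fdr_threshold FDR at which genes are flagged `predicted`.
#' @param use_filter Apply the SVD filter? Default `TRUE`.
#' @return A tibble with columns `gene_id`, `zbar`, `s`, `p`, `fdr`,
#'   `rank`, `predicted`, ordered by rank (descending score, ties broken
#'   by gene identifier).
#' @export
search_platform <- function(matrix, query, alpha = 0.5, kaiser = TRUE,
                            fdr_threshold = 0.01, use_filter = TRUE) {
  std <- standardize_genes(matrix)
  if (!all(query %in% rownames(std))) {
    stop("query gene(s) not present after standardization: ",
         paste(setdiff(query, rownames(std)), collapse = ", "),
         call. = FALSE)
  }
  target <- if (use_filter) {
    fact <- factorize_expression(std)
    L <- if (kaiser) kaiser_rank(fact) else length(fact$sigma)
    filter_matrix(fact, query_weights(fact, query, alpha = alpha), L = L)
  } else {
    std
  }
  res <- mean_fisher_correlation(target, query)
  res$s <- robust_standardize(res$zbar)
  res$p <- scores_to_pvalues(res$s)
  res$fdr <- adjust_bh(res$p)
  res <- res[order(-res$s, res$gene_id), ]
  res$rank <- seq_len(nrow(res))
  res$predicted <- res$fdr <= fdr_threshold
  res$zero_variance <- NULL
  tibble::as_tibble(res)
}

#' Search one or more expression datasets for cell type-enriched genes
#'
#' The end-to-end query-driven search. Each dataset (platform) is scored
#' independently with [search_platform()]; the per-platform robust z-scores
#' are then pooled across platforms by Stouffer's method and the pooled
#' p-values adjusted by Benjamini-Hochberg. Genes with pooled FDR at or
#' below `fdr_threshold` are flagged as predicted cell type-enriched.
#' Query genes are excluded from the ranked output and listed in the
#' result's `query_genes` field.
#'
#' @param datasets A single gene-by-sample matrix or a (preferably named)
#'   list of matrices, one per platform. Gene universes may differ; a gene
#'   is pooled over the platforms where it is present.
#' @param query Character vector of query gene identifiers; each must be
#'   present in at least one dataset. Platforms containing none of the
#'   query genes are skipped with a warning.
#' @inheritParams search_platform
#' @return An object of class `marker_search`: list with `pooled` (tibble:
#'   `gene_id`, `combined_z`, `combined_p`, `combined_fdr`, `n_platforms`,
#'   `rank`, `predicted`), `platforms` (named list of per-platform
#'   tibbles), `query_genes`, and `params`. Use [tidy()] for the pooled
#'   table and [glance()] for a one-row summary.
#' @examples
#' sim <- simulate_mixture(mixture_design(n_genes = 300, n_samples = 60,
#'                                        n_cell_types = 3, seed = 2))
#' q <- sim$truth$markers$gene_id[sim$truth$markers$cell_type == "cell_type_1"][1]
#' fit <- marker_search(sim$expression, q)
#' fit
#' @export
marker_search <- function(datasets, query, alpha = 0.5, kaiser = TRUE,
                          fdr_threshold = 0.01, use_filter = TRUE) {
  if (is.matrix(datasets)) datasets <- list(datasets)
  stopifnot(is.list(datasets), length(datasets) > 0)
  names(datasets) <- names(datasets) %||%
    paste0("platform_", seq_along(datasets))
  empty <- !nzchar(names(datasets))
  names(datasets)[empty] <- paste0("platform_", which(empty))
  query <- as.character(query)
  present <- lapply(datasets, function(m) intersect(query, rownames(m)))
  if (length(unique(unlist(present))) < length(query)) {
    stop("query gene(s) absent from every dataset: ",
         paste(setdiff(query, unlist(present)), collapse = ", "),
         call. = FALSE)
  }
  usable <- vapply(present, length, integer(1)) > 0
  if (!any(usable)) stop("no dataset contains a query gene", call. = FALSE)
  if (any(!usable)) {
    warning("skipping platform(s) with no query gene: ",
            paste(names(datasets)[!usable], collapse = ", "), call. = FALSE)
  }
  platforms <- purrr::imap(datasets[usable], function(m, nm) {
    search_platform(m, present[[nm]], alpha = alpha, kaiser = kaiser,
                    fdr_threshold = fdr_threshold, use_filter = use_filter)
  })
  pooled <- stouffer_pool(
    purrr::map(platforms, ~ dplyr::transmute(.x, gene_id = .data$gene_id,
                                             z = .data$s))
  )
  pooled$rank <- seq_len(nrow(pooled))
  pooled$predicted <- pooled$combined_fdr <= fdr_threshold
  structure(
    list(pooled = pooled, platforms = platforms, query_genes = query,
         params = list(alpha = alpha, kaiser = kaiser,
                       fdr_threshold = fdr_threshold,
                       use_filter = use_filter)),
    class = "marker_search"
  )
}

#' @export
print.marker_search <- function(x, ...) {
  cat("<marker_search> query: ", paste(x$query_genes, collapse = ", "),
      "\n  ", length(x$platforms), " platform(s), ",
      nrow(x$pooled), " genes scored, ",
      sum(x$pooled$predicted), " predicted at FDR <= ",
      x$params$fdr_threshold, "\n", sep = "")
  print(utils::head(x$pooled, 10))
  invisible(x)
}
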