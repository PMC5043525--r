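#' Derive a fold-change gold standard from purified expression profiles
#'
#' Given expression profiles of purified cell populations, declares a gene
#' positive when its mean expression in the target samples is at least
#' `fold_threshold` times its mean in the remaining samples ("at least" is
#' read inclusively: the exact boundary qualifies). With `scale = "log2"`
#' the rule is applied as a difference of means of at least
#' `log2(fold_threshold)`.
#'
#' @param profiles Gene-by-sample matrix of purified-population profiles.
#' @param target_samples Sample identifiers of the target cell type.
#' @param fold_threshold Fold-change cutoff (default 3, i.e. "at least
#'   threefold higher").
#' @param scale `"linear"` (intensities) or `"log2"` (log intensities).
#' @param label Provenance label.
#' @return An object of class `gold_standard`: list with `positives`,
#'   `universe`, `label`.
#' @examples
#' m <- rbind(a = c(9, 9, 3, 3), b = c(4, 4, 3, 3))
#' colnames(m) <- c("t1", "t2", "o1", "o2")
#' derive_gold_standard(m, c("t1", "t2"))$positives
#' @export
derive_gold_standard <- function(profiles, target_samples,
                                 fold_threshold = 3,
                                 scale = c("linear", "log2"),
                                 label = "gold_standard") {
  scale <- match.arg(scale)
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            fold_threshold > 0)
  if (length(target_samples) == 0) {
    stop("target sample set is empty", call. = FALSE)
  }
  missing <- setdiff(target_samples, colnames(profiles))
  if (length(missing) > 0) {
    stop("target sample(s) not in profiles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  others <- setdiff(colnames(profiles), target_samples)
  if (length(others) == 0) {
    stop("no non-target samples to compare against", call. = FALSE)
  }
  mt <- rowMeans(profiles[, target_samples, drop = FALSE])
  mo <- rowMeans(profiles[, others, drop = FALSE])
  pos <- if (scale == "linear") mt >= fold_threshold * mo
         else mt - mo >= log2(fold_threshold)
  positives <- rownames(profiles)[pos]
  if (length(positives) == 0) {
    stop("no gene meets the fold threshold; gold standard would be empty",
         call. = FALSE)
  }
  structure(list(positives = positives, universe = rownames(profiles),
                 label = label),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> '", x$label, "': ", length(x$positives),
      " positives in a universe of ", length(x$universe), "\n", sep = "")
  invisible(x)
}

#' Construct a gold standard from explicit gene sets
#'
#' @param positives,universe Character vectors; `positives` must be a
#'   non-empty subset of `universe`.
#' @param label Provenance label.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(positives, universe, label = "gold_standard") {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  if (length(positives) == 0) stop("positives are empty", call. = FALSE)
  if (!all(positives %in% universe)) {
    stop("positives must be a subset of the universe", call. = FALSE)
  }
  structure(list(positives = positives, universe = universe, label = label),
            class = "gold_standard")
}

#' Precision-recall curve of a ranked gene list
#'
#' Walks the ranking from the top and records, at each prefix, the
#' precision (fraction of retrieved genes that are positives) and recall
#' (fraction of all positives retrieved). Genes outside the gold-standard
#' universe are excluded before computation; positives never retrieved
#' still count in the recall denominator.
#'
#' @param ranked_genes Character vector, best first.
#' @param gold A `gold_standard`.
#' @return A tibble of class `pr_curve` with columns `rank`, `gene_id`,
#'   `hit`, `recall`, `precision`, and attributes `n_positives`,
#'   `n_ranked`.
#' @export
precision_recall <- function(ranked_genes, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  ranked <- ranked_genes[ranked_genes %in% gold$universe]
  if (length(ranked) == 0) {
    stop("ranking is empty after restricting to the universe", call. = FALSE)
  }
  hit <- ranked %in% gold$positives
  tp <- cumsum(hit)
  n_pos <- length(gold$positives)
  out <- tibble::tibble(
    rank = seq_along(ranked), gene_id = ranked, hit = hit,
    recall = tp / n_pos, precision = tp / seq_along(ranked)
  )
  class(out) <- c("pr_curve", class(out))
  attr(out, "n_positives") <- n_pos
  attr(out, "n_ranked") <- length(ranked)
  out
}

#' Area under the precision-recall curve
#'
#' The step-wise, interpolation-free estimator (average precision): the sum
#' of the precision at each retrieved positive, divided by the total number
#' of positives. Positives missing from the ranking contribute zero, so
#' the value is penalized for incomplete rankings.
#'
#' @param x A `pr_curve` from [precision_recall()], or a ranked character
#'   vector (in which case `gold` must be supplied).
#' @param gold A `gold_standard`, when `x` is a ranking.
#' @return A number in \[0, 1\].
#' @examples
#' g <- gold_standard("a", c("a", "b", "c"))
#' aupr(c("a", "b", "c"), g)
#' @export
aupr <- function(x, gold = NULL) {
  if (!inherits(x, "pr_curve")) {
    x <- precision_recall(x, gold)
  }
  sum(x$precision[x$hit]) / attr(x, "n_positives")
}

#' One-sided Fisher's exact test for gene-set enrichment
#'
#' Tests whether `hits` and `candidates` overlap more than expected by
#' chance within `universe`, via the exact hypergeometric upper tail of the
#' 2x2 table (in both; hits only; candidates only; neither).
#'
#' @param hits,candidates Character vectors, subsets of `universe`.
#' @param universe Character vector defining the background.
#' @return A one-row tibble: `n_overlap`, `n_hits`, `n_candidates`,
#'   `n_universe`, `odds_ratio` (conditional MLE), `p_value` (one-sided,
#'   greater).
#' @examples
#' u <- paste0("g", 1:100)
#' enrichment_fisher(u[1:10], u[1:15], u)
#' @export
enrichment_fisher <- function(hits, candidates, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  hits <- unique(as.character(hits))
  candidates <- unique(as.character(candidates))
  if (!all(hits %in% universe) || !all(candidates %in% universe)) {
    stop("hits and candidates must be subsets of the universe",
         call. = FALSE)
  }
  a <- length(intersect(hits, candidates))
  b <- length(hits) - a
  cc <- length(candidates) - a
  d <- length(universe) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                           alternative = "greater")
  tibble::tibble(n_overlap = a, n_hits = length(hits),
                 n_candidates = length(candidates),
                 n_universe = length(universe),
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
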