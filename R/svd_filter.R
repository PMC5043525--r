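#' Standardize each gene to mean 0, standard deviation 1
#'
#' Scales every row of the matrix so that downstream factorization sees
#' only co-variation structure, not absolute expression level. Sample
#' standard deviation (divisor n - 1) is used, consistent with the Pearson
#' correlation denominators used later. Rows with zero variance carry no
#' co-variation signal and are removed and reported.
#'
#' @param matrix Numeric gene-by-sample matrix, n >= 2 samples.
#' @return The standardized matrix. Removed zero-variance gene identifiers
#'   are recorded in the `"removed"` attribute (and reported in a warning).
#' @examples
#' standardize_genes(rbind(g1 = c(1, 2, 3), g2 = c(4, 0, 2)))
#' @export
standardize_genes <- function(matrix) {
  stopifnot(is.matrix(matrix))
  n <- ncol(matrix)
  if (n < 2) stop("at least 2 samples required", call. = FALSE)
  mu <- rowMeans(matrix)
  centered <- matrix - mu
  s <- sqrt(rowSums(centered^2) / (n - 1))
  flat <- s < 1e-12
  if (all(flat)) {
    stop("all rows have zero variance; nothing to standardize", call. = FALSE)
  }
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s) removed: ",
            paste(utils::head(rownames(matrix)[flat], 10), collapse = ", "),
            call. = FALSE)
  }
  out <- centered[!flat, , drop = FALSE] / s[!flat]
  attr(out, "removed") <- rownames(matrix)[flat]
  out
}

#' Thin singular value decomposition of a standardized matrix
#'
#' Factors X = U diag(sigma) V^T with orthonormal singular vectors and
#' singular values in non-increasing order. The thin factorization
#' (rank <= min(m, n)) is equivalent to the full one for reconstruction.
#'
#' @param matrix Standardized gene-by-sample matrix.
#' @return An object of class `expr_svd`: list with `U` (m x r gene
#'   loadings), `V` (n x r sample loadings), `sigma` (r singular values),
#'   `gene_ids`, `sample_ids`.
#' @export
factorize_expression <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2, ncol(matrix) >= 2)
  s <- tryCatch(svd(matrix),
                error = function(e) {
                  stop("SVD failed to converge: ", conditionMessage(e),
                       call. = FALSE)
                })
  structure(
    list(U = s$u, V = s$v, sigma = s$d,
         gene_ids = rownames(matrix), sample_ids = colnames(matrix)),
    class = "expr_svd"
  )
}

#' @export
print.expr_svd <- function(x, ...) {
  cat("<expr_svd> ", length(x$gene_ids), " genes x ", length(x$sample_ids),
      " samples, rank ", length(x$sigma), "\n", sep = "")
  invisible(x)
}

#' Number of singular vectors retained under Kaiser's criterion
#'
#' Keeps the singular vectors that each account for more variance than an
#' average single sample in the original dataset, i.e. those k with
#' sigma_k^2 strictly greater than (sum_j sigma_j^2) / n_samples. At least
#' one vector is always retained so the filter never returns an all-zero
#' matrix; ties at exactly the threshold fail the strict inequality.
#'
#' @param fact An `expr_svd` factorization.
#' @param n_samples Number of samples in the original dataset.
#' @param min_rank Lower bound on the retained rank (default 1).
#' @return Integer L, the retained rank.
#' @examples
#' f <- structure(list(sigma = c(4, 2, 2, 0),
#'                     sample_ids = letters[1:4]), class = "expr_svd")
#' kaiser_rank(f)  # threshold 24/4 = 6; only 16 > 6, so L = 1
#' @export
kaiser_rank <- function(fact, n_samples = length(fact$sample_ids),
                        min_rank = 1L) {
  sig2 <- fact$sigma^2
  threshold <- sum(sig2) / n_samples
  max(as.integer(min_rank), sum(sig2 > threshold))
}

#' Query-adaptive weights for the singular values
#'
#' For each singular vector k, the gene loadings (column k of U) are
#' standardized to mean 0, sd 1 across all genes, and the weight is the sum
#' over query genes of the hyperbolic tangent of their standardized
#' loadings: w_k = sum_g tanh(u_k^g). Vectors on which the query genes sit
#' near the bulk of the genome get |w_k| near 0 and are smoothly filtered
#' out; the tanh caps the influence of any single extreme loading, so
#' |w_k| <= number of query genes. The filtered spectrum is
#' sigma'_k = sigma_k^alpha * |w_k|, where the exponent alpha in [0, 1]
#' flattens the raw spectrum (alpha = 1 leaves it unscaled, alpha = 0
#' equalizes all singular values).
#'
#' @param fact An `expr_svd` factorization.
#' @param query Query gene identifiers (matched against `fact$gene_ids`) or
#'   row indices.
#' @param alpha Singular-value exponent in \[0, 1\]. Default 0.5.
#' @return An object of class `filter_weights`: list with `w`,
#'   `sigma`, `sigma_filtered`, `alpha`, `query_rows`.
#' @export
query_weights <- function(fact, query, alpha = 0.5) {
  stopifnot(inherits(fact, "expr_svd"))
  if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (length(query) == 0) stop("query set is empty", call. = FALSE)
  if (is.character(query)) {
    rows <- match(query, fact$gene_ids)
    if (anyNA(rows)) {
      stop("query gene(s) not present in matrix: ",
           paste(query[is.na(rows)], collapse = ", "), call. = FALSE)
    }
  } else {
    rows <- as.integer(query)
    if (any(rows < 1 | rows > nrow(fact$U))) {
      stop("query row index out of range", call. = FALSE)
    }
  }
  u_std <- scale(fact$U)  # mean 0, sample sd 1 per column, across all genes
  w <- colSums(tanh(u_std[rows, , drop = FALSE]))
  structure(
    list(w = w, sigma = fact$sigma,
         sigma_filtered = fact$sigma^alpha * abs(w),
         alpha = alpha, query_rows = rows),
    class = "filter_weights"
  )
}

#' Reconstruct the filtered expression matrix
#'
#' Transforms the data back from the truncated, re-weighted factorization:
#' X' = U\[, 1:L\] diag(sigma') V\[, 1:L\]^T with
#' sigma'_k = sigma_k^alpha * |w_k|. Because only |w_k| enters, the result
#' is invariant to the sign gauge of each singular-vector pair.
#'
#' @param fact An `expr_svd` factorization.
#' @param weights A `filter_weights` object from [query_weights()].
#' @param L Retained rank, typically from [kaiser_rank()].
#' @return The filtered gene-by-sample matrix, with a `"spectrum"`
#'   attribute: a tibble of `k`, `sigma`, `w`, `sigma_filtered`,
#'   `retained`.
#' @export
filter_matrix <- function(fact, weights, L = kaiser_rank(fact)) {
  stopifnot(inherits(fact, "expr_svd"), inherits(weights, "filter_weights"))
  r <- length(fact$sigma)
  if (L < 1) stop("retained rank L must be at least 1", call. = FALSE)
  if (L > r) stop("retained rank L exceeds factorization rank ", r,
                  call. = FALSE)
  keep <- seq_len(L)
  sf <- weights$sigma_filtered[keep]
  out <- fact$U[, keep, drop = FALSE] %*%
    (sf * t(fact$V[, keep, drop = FALSE]))
  dimnames(out) <- list(fact$gene_ids, fact$sample_ids)
  attr(out, "spectrum") <- tibble::tibble(
    k = seq_len(r), sigma = fact$sigma, w = weights$w,
    sigma_filtered = weights$sigma_filtered,
    retained = seq_len(r) <= L
  )
  out
}

#' Standardize, factorize and filter an expression matrix in one step
#'
#' Convenience wrapper running [standardize_genes()],
#' [factorize_expression()], [kaiser_rank()], [query_weights()] and
#' [filter_matrix()] in sequence. The Kaiser truncation is decided from the
#' original (unweighted) spectrum, since the criterion refers to variance
#' accounting in the original dataset; query weighting is applied to the
#' retained vectors.
#'
#' @inheritParams query_weights
#' @param matrix Raw gene-by-sample matrix (log-scale values).
#' @param kaiser Apply Kaiser truncation? Default `TRUE` (otherwise the
#'   full rank is kept).
#' @param min_rank Lower bound on the retained rank.
#' @return The filtered matrix (see [filter_matrix()] for attributes).
#' @examples
#' sim <- simulate_mixture(mixture_design(n_genes = 200, n_samples = 40,
#'                                        n_cell_types = 2, seed = 1))
#' q <- sim$truth$markers$gene_id[1]
#' xf <- svd_filter(sim$expression, q)
#' @export
svd_filter <- function(matrix, query, alpha = 0.5, kaiser = TRUE,
                       min_rank = 1L) {
  std <- standardize_genes(matrix)
  fact <- factorize_expression(std)
  L <- if (kaiser) kaiser_rank(fact, min_rank = min_rank)
       else length(fact$sigma)
  w <- query_weights(fact, query, alpha = alpha)
  filter_matrix(fact, w, L = L)
}
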