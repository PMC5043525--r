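#' Design of a synthetic mixed-tissue expression experiment
#'
#' Describes the generative model for [simulate_mixture()]: each gene draws
#' a standard-normal baseline expression level shared across the K latent
#' cell types, and disjoint sets of planted marker genes have their
#' own-type profile raised by `log2_fold_change` — so the planted markers
#' are exactly the cell type-enriched genes and all other genes are true
#' negatives. Every sample is a convex combination of the type profiles
#' with Dirichlet-distributed proportions, plus per-gene batch offsets
#' (unwanted structured variation, as in multi-experiment compendia) and
#' iid Gaussian noise — emulating bulk samples whose cell-type composition
#' varies from sample to sample.
#'
#' The default design plants 5 cell types of 50 markers each in 2000 genes
#' across 200 samples at a log2 fold change of 2 (fourfold), with one rare
#' type whose Dirichlet concentration gives it a mean proportion of 0.05,
#' batch structure of 5 batches with 0.5 sd offsets, and residual noise of
#' 0.5 sd on the log2 scale.
#'
#' @param n_genes,n_samples Matrix dimensions m and n.
#' @param n_cell_types Number K of latent cell types.
#' @param markers_per_type Planted markers per type; `K * markers_per_type`
#'   must not exceed `n_genes`.
#' @param log2_fold_change Elevation of a marker's own-type profile, in
#'   log2 units.
#' @param proportion_prior Dirichlet concentration vector of length K. The
#'   default gives types 1..K-1 concentration 1 and the last type a
#'   concentration making its mean proportion 0.05 (a rare cell type).
#' @param noise_sd Residual noise sd (log2 scale).
#' @param n_batches,batch_sd Number of sample batches and the sd of the
#'   per-gene, per-batch offsets; `n_batches = 1` or `batch_sd = 0`
#'   disables batch structure. The defaults (5 batches, sd 0.5) give the
#'   batch effects the same magnitude as the residual noise, typical of
#'   expression compendia assembled from several experiments.
#' @param mixing `"log2"` mixes profiles as a convex combination on the
#'   log2 scale (the default simplification; per-gene standardization
#'   downstream makes only co-variation matter); `"linear"` exponentiates,
#'   mixes intensities, and returns to log2.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class `mixture_design` (a validated list).
#' @export
mixture_design <- function(n_genes = 2000, n_samples = 200,
                           n_cell_types = 5, markers_per_type = 50,
                           log2_fold_change = 2,
                           proportion_prior = NULL,
                           noise_sd = 0.5, n_batches = 5, batch_sd = 0.5,
                           mixing = c("log2", "linear"), seed = 1) {
  mixing <- match.arg(mixing)
  if (is.null(proportion_prior)) {
    proportion_prior <- if (n_cell_types > 1) {
      c(rep(1, n_cell_types - 1), 0.05 * (n_cell_types - 1) / 0.95)
    } else {
      1
    }
  }
  d <- list(n_genes = as.integer(n_genes),
            n_samples = as.integer(n_samples),
            n_cell_types = as.integer(n_cell_types),
            markers_per_type = as.integer(markers_per_type),
            log2_fold_change = log2_fold_change,
            proportion_prior = proportion_prior,
            noise_sd = noise_sd, n_batches = as.integer(n_batches),
            batch_sd = batch_sd, mixing = mixing, seed = as.integer(seed))
  with(d, {
    stopifnot(n_genes >= 2, n_samples >= 2, n_cell_types >= 1,
              markers_per_type >= 1,
              n_cell_types * markers_per_type <= n_genes,
              length(proportion_prior) == n_cell_types,
              all(proportion_prior > 0),
              log2_fold_change >= 0, noise_sd >= 0,
              n_batches >= 1, batch_sd >= 0)
  })
  structure(d, class = "mixture_design")
}

#' Simulate a mixed-tissue expression matrix with planted markers
#'
#' Draws one baseline level b_g ~ N(0, 1) per gene (shared across cell
#' types, so non-marker genes carry no cell type-dependent signal), raises
#' each marker's own-type profile by the design's log2 fold change, mixes
#' the type profiles per sample with Dirichlet proportions, and adds
#' per-gene batch offsets and Gaussian noise. Identical design (including
#' seed) yields an identical matrix and truth table.
#'
#' @param design A [mixture_design()].
#' @return A list with `expression` (gene-by-sample matrix) and `truth`, an
#'   object of class `synthetic_truth`: `markers` (tibble `gene_id`,
#'   `cell_type`), `proportions` (sample-by-type matrix, rows summing to
#'   1), `batches` (tibble `sample_id`, `batch`).
#' @examples
#' sim <- simulate_mixture(mixture_design(n_genes = 100, n_samples = 30,
#'                                        n_cell_types = 2, seed = 7))
#' head(sim$truth$markers)
#' @export
simulate_mixture <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  d <- design
  withr::with_seed(d$seed, {
    m <- d$n_genes; n <- d$n_samples; K <- d$n_cell_types
    gene_ids <- paste0("g", formatC(seq_len(m), width = nchar(m), flag = "0"))
    sample_ids <- paste0("s", formatC(seq_len(n), width = nchar(n), flag = "0"))
    types <- paste0("cell_type_", seq_len(K))

    profiles <- matrix(stats::rnorm(m), m, K,
                       dimnames = list(gene_ids, types))
    marker_rows <- sample.int(m, K * d$markers_per_type)
    marker_type <- rep(seq_len(K), each = d$markers_per_type)
    profiles[cbind(marker_rows, marker_type)] <-
      profiles[cbind(marker_rows, marker_type)] + d$log2_fold_change

    # Dirichlet proportions via normalized gammas
    g <- matrix(stats::rgamma(n * K, shape = rep(d$proportion_prior,
                                                 each = n)), n, K)
    props <- g / rowSums(g)
    dimnames(props) <- list(sample_ids, types)

    x <- if (d$mixing == "log2") {
      profiles %*% t(props)
    } else {
      log2(2^profiles %*% t(props))
    }

    batch <- rep(seq_len(d$n_batches), length.out = n)
    if (d$n_batches > 1 && d$batch_sd > 0) {
      offsets <- matrix(stats::rnorm(m * d$n_batches, sd = d$batch_sd),
                        m, d$n_batches)
      x <- x + offsets[, batch]
    }
    if (d$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(m * n, sd = d$noise_sd), m, n)
    }
    dimnames(x) <- list(gene_ids, sample_ids)

    truth <- structure(
      list(
        markers = tibble::tibble(
          gene_id = gene_ids[marker_rows],
          cell_type = types[marker_type]
        ) |> dplyr::arrange(.data$cell_type, .data$gene_id),
        proportions = props,
        batches = tibble::tibble(sample_id = sample_ids, batch = batch),
        design = d
      ),
      class = "synthetic_truth"
    )
    list(expression = x, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$markers), " planted markers in ",
      x$design$n_cell_types, " cell type(s)\n", sep = "")
  print(dplyr::count(x$markers, .data$cell_type))
  invisible(x)
}

#' Simulate a pure-noise expression matrix
#'
#' An iid standard-normal gene-by-sample matrix: the null model under which
#' the search statistic should be calibrated (equivalent to scrambling
#' sample labels, which destroys all co-expression structure).
#'
#' @param m,n Numbers of genes and samples.
#' @param seed Integer seed.
#' @return A numeric matrix with gene and sample identifiers.
#' @examples
#' x <- simulate_null(100, 10, seed = 1)
#' @export
simulate_null <- function(m, n, seed = 1) {
  withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(m * n), m, n,
           dimnames = list(
             paste0("g", formatC(seq_len(m), width = nchar(m), flag = "0")),
             paste0("s", formatC(seq_len(n), width = nchar(n), flag = "0"))
           ))
  })
}
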