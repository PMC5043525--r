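# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Step-up BH adjustment, straight from the definition.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Step-down Holm adjustment, straight from the definition.
ref_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# One-sided (greater) Fisher's exact p for table [a, b; c, d] by direct
# summation of hypergeometric terms.
ref_fisher_greater <- function(a, b, c, d) {
  n_hits <- a + b
  n_cand <- a + c
  n_tot <- a + b + c + d
  ks <- seq(a, min(n_hits, n_cand))
  sum(exp(lchoose(n_hits, ks) + lchoose(n_tot - n_hits, n_cand - ks) -
            lchoose(n_tot, n_cand)))
}

# Average-precision AUPR recomputed by an explicit loop.
ref_aupr <- function(ranked, positives) {
  tp <- 0; total <- 0
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% positives) {
      tp <- tp + 1
      total <- total + tp / i
    }
  }
  total / length(positives)
}

# Tiny deterministic expression fixture.
toy_matrix <- function(m = 6, n = 5, seed = 11) {
  simulate_null(m, n, seed = seed)
}

# A reduced planted-marker benchmark for unit tests (same generative
# model as the default design, smaller).
small_design <- function(seed = 1, fold = 2) {
  mixture_design(n_genes = 500, n_samples = 80, n_cell_types = 3,
                 markers_per_type = 25, log2_fold_change = fold,
                 seed = seed)
}

search_aupr <- function(sim, use_filter = TRUE, cell_type = "cell_type_1") {
  mk <- sim$truth$markers
  q <- mk$gene_id[mk$cell_type == cell_type][1]
  fit <- marker_search(sim$expression, q, use_filter = use_filter)
  pos <- setdiff(mk$gene_id[mk$cell_type == cell_type], q)
  gs <- gold_standard(pos, setdiff(rownames(sim$expression), q))
  aupr(tidy(fit)$gene_id, gs)
}
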