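test_that("positional candidates follow the centered-window overlap rule", {
  snps <- snp_records("rs1", "chr1", 1e6)
  genes <- gene_intervals(c("inside", "edge_in", "edge_out", "other_chr"),
                          c("chr1", "chr1", "chr1", "chr2"),
                          c(999000, 1005000, 1010001, 1005000),
                          c(999500, 1020000, 1020000, 1020000))
  out <- positional_candidates(snps, genes, window_bp = 20000)
  # window spans [990000, 1010000]
  expect_setequal(out$gene_id, c("inside", "edge_in"))

  # window 0: only genes containing the SNP position
  genes0 <- gene_intervals(c("covers", "misses"), c("chr1", "chr1"),
                           c(999999, 1000001), c(1000001, 1000500))
  out0 <- positional_candidates(snps, genes0, window_bp = 0)
  expect_identical(out0$gene_id, "covers")
})

test_that("positional candidates match an all-pairs loop on random input", {
  set.seed(19)
  snps <- snp_records(paste0("rs", 1:50),
                      sample(c("chr1", "chr2"), 50, replace = TRUE),
                      sample.int(5e6, 50))
  start <- sample.int(5e6, 50)
  genes <- gene_intervals(paste0("gene", 1:50),
                          sample(c("chr1", "chr2"), 50, replace = TRUE),
                          start, start + sample.int(2e5, 50))
  w <- 20000
  got <- positional_candidates(snps, genes, window_bp = w)
  manual <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] == genes$chrom[j] &&
          genes$start[j] <= snps$pos[i] + w / 2 &&
          genes$end[j] >= snps$pos[i] - w / 2) {
        manual[[length(manual) + 1]] <-
          c(snps$snp_id[i], genes$gene_id[j])
      }
    }
  }
  manual <- do.call(rbind, manual)
  expect_identical(nrow(got), nrow(manual))
  expect_setequal(paste(got$snp_id, got$gene_id),
                  paste(manual[, 1], manual[, 2]))
})

test_that("BED input is converted from 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999999\t1000000\trs1"), f)
  snps <- read_snp_bed(f)
  expect_identical(snps$pos, 1e6)

  g <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tgeneA"), g)
  genes <- read_gene_bed(g)
  expect_identical(genes$start, 101)
  expect_identical(genes$end, 200)
})

test_that("phase 1 flags maximally enriched cell types and handles ties", {
  universe <- paste0("g", 1:20000)
  top <- universe[1:200]
  preds <- list(
    enriched = universe,                      # top 200 = candidates
    unrelated = rev(universe)
  )
  res <- phase1_priority_cell_types(preds, gwas_candidates = top,
                                    universe = universe)
  enr <- res[res$cell_type == "enriched", ]
  expect_true(enr$priority)
  expect_lt(enr$p_holm, 1e-100)
  expect_false(res$priority[res$cell_type == "unrelated"])

  # identical top lists tie deterministically: both reported, equal p
  preds2 <- list(a = universe, b = universe)
  res2 <- phase1_priority_cell_types(preds2, top, universe)
  expect_equal(res2$p_value[1], res2$p_value[2])
  expect_equal(res2$p_holm[1], res2$p_holm[2])
  expect_identical(nrow(res2), 2L)

  expect_error(phase1_priority_cell_types(preds, character(), universe),
               "empty")
})

test_that("phase 1 is calibrated under uniformly drawn candidates", {
  # reduced-size null calibration; the 100-simulation version runs in the
  # acceptance suite
  set.seed(55)
  universe <- paste0("g", 1:3000)
  preds <- lapply(1:6, function(i) sample(universe))
  names(preds) <- paste0("ct", 1:6)
  n_pass <- vapply(1:30, function(i) {
    cands <- sample(universe, 150)
    sum(phase1_priority_cell_types(preds, cands, universe)$priority)
  }, numeric(1))
  expect_gte(mean(n_pass == 0), 0.9)
})

test_that("phase 2 applies distance and FDR cutoffs inclusively", {
  snps <- snp_records("rs1", "chr1", 1e6)
  genes <- gene_intervals(c("at_edge", "beyond", "near_ok", "near_badfdr"),
                          rep("chr1", 4),
                          c(1250000, 1250001, 1010000, 1020000),
                          c(1260000, 1260000, 1015000, 1025000))
  pooled <- list(ct1 = tibble::tibble(
    gene_id = c("at_edge", "beyond", "near_ok", "near_badfdr"),
    combined_fdr = c(0.05, 0.05, 0.01, 0.11)
  ))
  out <- phase2_select_candidates(snps, genes, pooled)
  # nearest edge of at_edge is exactly 250000 bp away: included
  expect_setequal(out$gene_id, c("at_edge", "near_ok"))
  expect_identical(out$gene_id[1], "near_ok")  # sorted by fdr within snp
  expect_error(phase2_select_candidates(snps, genes, list()), "priority")
})

test_that("phase 2 equals an exhaustive filter loop on a toy locus", {
  set.seed(23)
  snps <- snp_records(c("rsA", "rsB"), c("chr1", "chr1"), c(5e5, 9e5))
  start <- sort(sample.int(15e5, 5))
  genes <- gene_intervals(paste0("gene", 1:5), rep("chr1", 5),
                          start, start + 20000)
  pooled <- list(
    ct1 = tibble::tibble(gene_id = paste0("gene", 1:5),
                         combined_fdr = runif(5, 0, 0.2)),
    ct2 = tibble::tibble(gene_id = paste0("gene", 1:5),
                         combined_fdr = runif(5, 0, 0.2))
  )
  maxd <- 250000; thr <- 0.1
  got <- phase2_select_candidates(snps, genes, pooled,
                                  max_distance_bp = maxd,
                                  fdr_threshold = thr)
  manual <- list()
  for (i in 1:2) for (j in 1:5) for (ct in names(pooled)) {
    d <- if (snps$pos[i] >= genes$start[j] && snps$pos[i] <= genes$end[j]) 0
         else min(abs(snps$pos[i] - genes$start[j]),
                  abs(snps$pos[i] - genes$end[j]))
    fdr <- pooled[[ct]]$combined_fdr[pooled[[ct]]$gene_id == genes$gene_id[j]]
    if (d <= maxd && fdr <= thr) {
      manual[[length(manual) + 1]] <-
        paste(snps$snp_id[i], genes$gene_id[j], ct)
    }
  }
  expect_setequal(paste(got$snp_id, got$gene_id, got$cell_type),
                  unlist(manual))
})

test_that("phase 2 output is monotone in the distance and FDR knobs", {
  set.seed(29)
  snps <- snp_records(paste0("rs", 1:5), rep("chr1", 5),
                      sample.int(3e6, 5))
  start <- sample.int(3e6, 20)
  genes <- gene_intervals(paste0("gene", 1:20), rep("chr1", 20),
                          start, start + 30000)
  pooled <- list(ct = tibble::tibble(gene_id = paste0("gene", 1:20),
                                     combined_fdr = runif(20, 0, 0.3)))
  key <- function(tbl) paste(tbl$snp_id, tbl$gene_id, tbl$cell_type)
  base <- phase2_select_candidates(snps, genes, pooled)
  wider <- phase2_select_candidates(snps, genes, pooled,
                                    max_distance_bp = 500000)
  looser <- phase2_select_candidates(snps, genes, pooled,
                                     fdr_threshold = 0.2)
  expect_true(all(key(base) %in% key(wider)))
  expect_true(all(key(base) %in% key(looser)))
})

test_that("the two-phase wrapper ties the pieces together", {
  set.seed(61)
  universe <- paste0("g", 1:2000)
  # genes tile chr1; the first 200 cluster near the SNPs
  start <- seq(1, by = 5000, length.out = 2000)
  genes <- gene_intervals(universe, "chr1", start, start + 2000)
  snps <- snp_records(paste0("rs", 1:30), "chr1",
                      sample(start[1:200] + 1000, 30))
  preds <- list(
    target = c(universe[1:200], sample(universe[201:2000])),
    decoy = rev(universe)
  )
  pooled <- list(
    target = tibble::tibble(gene_id = universe,
                            combined_fdr = c(rep(0.01, 200),
                                             rep(0.5, 1800))),
    decoy = tibble::tibble(gene_id = universe, combined_fdr = 0.5)
  )
  res <- prioritize_gwas(snps, genes, preds, pooled, universe)
  expect_s3_class(res, "gwas_prioritization")
  expect_true("target" %in% res$priority_cell_types)
  expect_false("decoy" %in% res$priority_cell_types)
  expect_true(all(tidy(res)$cell_type == "target"))
  expect_true(all(tidy(res)$fdr <= 0.1))
  expect_gt(nrow(tidy(res)), 0)
  expect_identical(glance(res)$n_priority, 1L)
})
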