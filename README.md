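# markermap

Infer cell type-enriched genes from bulk expression data of heterogeneous
samples, using one or a few known marker ("query") genes as the only
supervision.

## The problem

Bulk tissue expression is a mixture: each sample averages the profiles of
its constituent cell types, in proportions that vary from sample to
sample. Genes selectively expressed in one cell type therefore co-vary
with that type's (unobserved) abundance — and with each other. If you know
even one reliable marker of a cell type, the co-expression neighborhood of
that marker contains the rest of the cell type's gene program. The catch
is that in real compendia the leading axes of variation are tissue
composition and batch, not the cell type you care about, and plain
correlation with the query drowns for rare cell types.

markermap addresses this with a query-adaptive SVD filter. The
standardized matrix $X$ is factored as $X = U\Sigma V^{\mathsf T}$ and
rebuilt from singular values re-weighted as

$$\sigma_k' = \sigma_k^{\alpha} \, \lvert w_k \rvert, \qquad
  w_k = \sum_{g \in \text{query}} \tanh(u_k^g),$$

where $u_k^g$ is the query gene's standardized loading on singular vector
$k$: the exponent $\alpha$ (default 0.5) flattens the dominant directions,
the $\tanh$ weight silences directions in which the query genes do not
stand out from the genome, and Kaiser's criterion trims vectors carrying
less variance than an average single sample. On the filtered matrix every
gene is scored by its mean Fisher-transformed correlation with the query
genes, $\bar z_g = \tfrac{1}{2N}\sum_Q \ln\frac{1+\rho_{gQ}}{1-\rho_{gQ}}$,
robust-standardized as
$S_g = (\bar z_g - \mathrm{median})/(1.4826 \times \mathrm{MAD})$, and
converted to one-sided normal p-values with BH FDR control. Multiple
platforms are pooled per gene by Stouffer's method
($Z = \sum z_i/\sqrt{k}$). A two-phase GWAS module then uses these
predictions to prioritize candidate genes at disease loci (20 kb-window
enrichment of positional candidates in each cell type's top 200
predictions with Holm-adjusted Fisher tests, then selection of genes
within 250 kb of a SNP at pooled FDR ≤ 0.1).

The package also ships the surrounding toolkit: expression matrix I/O with
probeset collapsing and hierarchical identifier mapping, a synthetic
mixed-tissue simulator with planted markers (the test bed), and
precision–recall / AUPR / Fisher-enrichment evaluation. Results are
tibbles; fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

Simulate the default benchmark — 2000 genes, 200 mixed samples, 5 cell
types with 50 planted markers each (one type rare at a mean proportion of
5 %), batch structure and noise — then search with a single query marker
of cell type 1:

```r
library(markermap)

sim   <- simulate_mixture(mixture_design(seed = 1))
query <- with(sim$truth$markers, gene_id[cell_type == "cell_type_1"])[1]  # "g0018"
fit   <- marker_search(sim$expression, query)
fit
#> <marker_search> query: g0018
#>   1 platform(s), 1999 genes scored, 38 predicted at FDR <= 0.01
#> # A tibble: 10 × 7
#>    gene_id combined_z combined_p combined_fdr n_platforms  rank predicted
#>    <chr>        <dbl>      <dbl>        <dbl>       <int> <int> <lgl>
#>  1 g0360         7.58   1.73e-14     3.26e-11           1     1 TRUE
#>  2 g1095         7.50   3.26e-14     3.26e-11           1     2 TRUE
#>  3 g0589         6.97   1.63e-12     1.09e- 9           1     3 TRUE
#>  # ...
```

`combined_z` is the (Stouffer-pooled) robust z-score of the mean Fisher-z
correlation with the query; `predicted` flags genes at FDR ≤ 0.01. Of the
top 50 genes, 44 are planted markers of the queried cell type. Evaluating
the full ranking against the planted truth:

```r
pos <- setdiff(with(sim$truth$markers, gene_id[cell_type == "cell_type_1"]), query)
gs  <- gold_standard(pos, setdiff(rownames(sim$expression), query))
aupr(tidy(fit)$gene_id, gs)
#> [1] 0.9700779
```

The same search with the SVD filter bypassed
(`marker_search(..., use_filter = FALSE)`, i.e. plain query correlation)
reaches only AUPR 0.48 on this benchmark — the filter is what holds up
against the batch structure.

A thin command-line interface over the same functions is installed at
`inst/cli/markermap.R` with `search`, `simulate`, `evaluate` and `gwas`
subcommands.

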