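# sigscape

Functional annotation of the variation in single-cell RNA-seq data —
without requiring a clustering first.

Single-cell analyses usually end with a low-dimensional map of the cells
(PCA, scVI, a trajectory) and the question: *what biology does this
structure correspond to?*  Cluster-based workflows answer it only for
variation that falls along cluster boundaries.  `sigscape` answers it for
any smooth structure on the map, by testing libraries of gene signatures
for **local autocorrelation** on the cell–cell similarity graph.  It is
aimed at analysts who already have a normalized expression matrix, a
latent space or trajectory model, and signature collections (e.g. MSigDB
GMT files).

## The statistics at the core

**Corrected signature scores.**  For a signature with positive/negative
gene sets (coefficients ±1), the per-cell score is the signed mean of
log-scale expression,
s_j = (Σ_{g∈G_pos} e_gj − Σ_{g∈G_neg} e_gj) / (n + m),
z-normalized against the analytic moments of a random signature of the
same size and balance: E[R_j] = ((n−m)/(n+m))·ē_j and
var(R_j) = σ_j²/(n+m), where ē_j and σ_j² are the mean and population
variance of cell j's expression over all genes.  This removes the
correlation of naive scores with library size and detection rate.

**Graph autocorrelation.**  Cells are joined to their K = ⌈√N⌉ nearest
neighbours (Euclidean in the latent space, or geodesic along a trajectory's
milestone network) with Gaussian kernel weights w_ij = exp(−d_ij²/σ_i²),
σ_i set per cell from the distance to the K-th neighbour.  Each
signature's effect size is C′ = 1 − C, with C Geary's statistic on the
score ranks:

C = (N−1) Σ_i Σ_j w_ij (x_i − x_j)² / (2W Σ_i (x_i − x̄)²)

C′ ≈ 0 for noise, → 1 for scores that vary smoothly on the map.
Significance comes from an empirical null of random signatures matched in
size and sign balance (grouped by seeded k-means into 5 background
groups), pushed through the identical scoring→rank→C′ path:
p = (x+1)/(n_bg+1), BH-corrected.

**Companion tests.**  One-vs-all Wilcoxon rank-sum tests with AUROC effect
sizes for any cell labelling; a chi-squared / Cramér's V test of how
strongly categorical covariates (batch, donor) are localized on the graph,
built from kernel-weighted local label proportions; permutation tests for
numeric covariates; Spearman annotation of individual latent components;
and micro-pooling (Louvain + k-means on 20-dim PCA) that merges cells into
pools of ≤ P members so large datasets can be processed on pooled profiles
with consistent signature rankings.

See `vignettes/sigscape-methods.Rmd` for the full model description,
parameter defaults, and the design rationale behind the numerical choices.

## Worked example

Everything below is simulated, so it runs in seconds with no downloads.
We plant an interferon-response-like signature (+1 natural-log-unit shift
on 40 genes) in one of two clusters, add a random decoy signature, and ask
`sigscape` to annotate the dataset.

```r
library(sigscape)

sim <- simulate_clustered_dataset(
  n_cells = 600, n_genes = 1500, n_clusters = 2,
  planted = list(planted_signature("ifn_response", 40, clusters = 2, effect = 1)),
  seed = 42)
expr <- normalize_expression(sim$counts, mode = "median_umi")

set.seed(7)
signatures <- c(sim$signatures,
                list(random_set = gene_signature("random_set",
                       sample(rownames(expr), 40))))
meta <- sim$meta
meta$detection_rate <- colMeans(sim$counts > 0)

fit <- sigscape(expr, signatures, meta = meta,
                n_backgrounds = 200, n_permutations = 500, seed = 1)
fit
#> <sigscape_result>
#>   2 signatures x 600 cells, K = 25 (latent graph)
#>   top autocorrelated signature: ifn_response (C' = 0.624, FDR = 0.00995)

tidy(fit)
#> # A tibble: 2 × 5
#>   signature    c_prime p_value     fdr background_group
#>   <chr>          <dbl>   <dbl>   <dbl>            <int>
#> 1 ifn_response  0.624  0.00498 0.00995                1
#> 2 random_set    0.0403 0.488   0.488                  1
```

The planted signature is strongly autocorrelated on the latent map
(C′ = 0.62; its score ranks vary smoothly across the graph) and beats all
200 matched random signatures (p = 1/201), while the decoy sits at the
noise floor.  The same run also reports that the cluster label is sharply
localized on the graph while the donor label is not:

```r
tidy(fit, "meta_categorical")
#> # A tibble: 2 × 6
#>   variable cramers_v     chi2   dof p_value   fdr
#>   <chr>        <dbl>    <dbl> <dbl>   <dbl> <dbl>
#> 1 cluster    0.644   2601.        1   0     0
#> 2 donor      0.00480    0.145     1   0.704 0.704

glance(fit)
#> # A tibble: 1 × 7
#>   n_signatures n_cells     K mode   n_autocorrelated n_differential max_c_prime
#>          <int>   <int> <int> <chr>             <int>          <int>       <dbl>
#> 1            2     600    25 latent                1              2       0.624
```

Other entry points: `tidy(fit, "differential")` (1-vs-all AUROC per
signature and group), `tidy(fit, "meta_numeric")` (permutation
autocorrelation of numeric covariates such as the detection rate),
`tidy(fit, "components")` (per-latent-dimension annotation),
`autoplot(fit)` and `plot_signature_scores(fit, "ifn_response")` for
figures, `write_results_bundle(fit, dir)` + `render_report(dir)` for a
TSV bundle and a static HTML report, and `run_from_config("run.yaml")` to
drive everything from a config file.  Trajectory data enters through
`read_trajectory()` / `knn_from_trajectory()`; large datasets through
`micropool()`.

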