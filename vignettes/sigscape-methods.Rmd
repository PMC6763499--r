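---
title: "Methods: signature scores, graph autocorrelation, and micro-pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scores, graph autocorrelation, and micro-pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sigscape annotates the axes of variation in a single-cell RNA-seq dataset
with biological meaning, without requiring the cells to be clustered
first.  The inputs are a normalized expression matrix, a library of gene
signatures, and a cell–cell similarity structure (a latent space or a
trajectory).  The outputs are ranked tables: which signatures vary
*coherently* across the cell manifold, which are differential between
labelled groups, and which categorical covariates (batch, donor) are
localized on the manifold.

This vignette records the statistical model, the tunable parameters and
their defaults, the numerical choices, and what the simulation-based tests
do and do not establish.

## Signature scores

A signature is a gene set, optionally signed into a positive set
$G_{pos}$ and a negative set $G_{neg}$ (gene coefficients are restricted
to $\pm 1$).  For cell $j$ the raw score is

$$ s_j = \frac{\sum_{g \in G_{pos}} e_{gj} - \sum_{g \in G_{neg}} e_{gj}}
             {|G_{pos}| + |G_{neg}|} $$

where $e_{gj}$ is normalized, log-scale expression.  Signature genes
absent from the matrix are dropped *before* the denominator is formed, so
$n = |G_{pos}|$ and $m = |G_{neg}|$ always count genes actually used;
matching is case-insensitive and exact otherwise (no identifier-version
stripping).

Raw scores correlate with per-cell technical covariates (library size,
detection rate).  They are therefore z-normalized against the analytic
moments of a *random* signature with the same $n$ and $m$, drawn from the
matrix's gene universe:

$$ \mathrm{E}[R_j] = \frac{n - m}{n + m}\,\bar e_j, \qquad
   \mathrm{var}(R_j) = \frac{\sigma_j^2}{n + m}, \qquad
   s'_j = \frac{s_j - \mathrm{E}[R_j]}{\mathrm{var}(R_j)^{1/2}} $$

with $\bar e_j$ and $\sigma_j^2$ the mean and population ($1/N$) variance
of cell $j$'s expression over **all** genes of the (filtered) matrix.
The variance formula treats the sampled genes as independent; sampling
without replacement from a finite universe shrinks the true variance by
$(G - n - m)/(G - 1)$.  We implement the formula as printed and do not
apply this correction — for realistic signature sizes ($\lesssim$ a few
hundred genes against universes of thousands) the factor is within a few
percent of 1, and the calibration tests bound the effect.  Cells whose
expression is constant across genes have $\sigma_j^2 = 0$; they cannot be
corrected and are scored 0 with a warning (all-zero cells are already
dropped at normalization for this reason).

**Calibration testing.**  The suite verifies that corrected scores of
random signatures have per-cell mean $\approx 0$ and variance $\approx 1$.
The mean check uses a stratified draw — signatures are consecutive blocks
of fresh random permutations of the gene universe, so every gene is used
equally often.  Each signature is still marginally a uniform random set,
but the per-cell average of raw scores then equals $\bar e_j$ *exactly*,
which turns the mean check into a noise-free test of the expectation
formula: it fails if and only if $\mathrm{E}[R_j]$ is implemented wrong.
The variance check keeps ordinary Monte-Carlo noise and uses signatures
of 20 genes against a 2,000-gene universe (finite-population factor
0.99).

## Local autocorrelation on the cell–cell graph

The question "does this signature explain the structure of the latent
space?" is answered with Geary's C computed on the *ranks* of the
corrected scores (average ranks for ties; ranks make the statistic
invariant to monotone transforms of the score):

$$ C = \frac{(N-1) \sum_i \sum_j w_{ij} (x_i - x_j)^2}
            {2 W \sum_i (x_i - \bar x)^2} $$

Reported is $C' = 1 - C$: 0 means no local autocorrelation, 1 maximal
smoothness on the graph.  The sum runs over the directed stored pairs
$(i, j \in \mathrm{KNN}(i))$ exactly as written; weights are not
symmetrized (a $(w_{ij}+w_{ji})/2$ variant would change $C'$ only
marginally on KNN graphs and is not implemented).

**The graph.**  Each cell is linked to its $K$ nearest neighbours,
$K = \lceil\sqrt{N}\rceil$ by default — results are quite insensitive to
$K$, and the suite checks that $C'$ *rankings* across
$K \in \{10, \dots, 2\sqrt N\}$ stay rank-correlated above 0.9.
Neighbour weights decay as $w_{ij} = \exp(-d_{ij}^2 / \sigma_i^2)$.  The
bandwidth is per-cell and adaptive: $\sigma_i$ is the distance to the
$K$-th neighbour, so the kernel argument is dimensionless and the $K$-th
neighbour always receives weight $e^{-1}$.  Because the source
description of this kernel can also be read with $\sigma_i^2$ *equal* to
that distance, the un-squared variant is available as
`bandwidth = "literal"`; the default is `"squared"`.  Rows whose $K$-th
neighbour distance is 0 (duplicated points) fall back to uniform weights
with a warning.  A cell is never its own neighbour.  Distance ties at the
$K$ boundary break by cell index, making graphs deterministic.

KNN search is exact (blocked dense distance computation).  At the problem
sizes this package targets in-memory (up to a few tens of thousands of
cells, and a few thousand after micro-pooling) exactness is affordable
and removes a source of irreproducibility.

**Trajectories.**  When the similarity structure is a trajectory — a
milestone network with edge lengths plus per-cell (edge, progress)
positions, the common abstraction that trajectory-inference wrappers emit
— distances are geodesic: path length through the network between the two
cells' positions, with cells on a shared edge also connected directly
along it.  The implementation reduces cell–cell distance to a minimum
over the two exit milestones of one cell, using precomputed
milestone-to-milestone shortest paths; tests verify it against an
independent Dijkstra run on a cell-augmented graph.  Disconnected
networks are rejected (with the components named) rather than silently
producing infinite distances.

## Significance: grouped random-signature nulls

An observed $C'$ is compared with an empirical null of random signatures
pushed through the *identical* pipeline — corrected scoring, rank
transform, same graph — so the null reflects everything the statistic is
exposed to, not just the statistic.  The p-value is

$$ p = \frac{x + 1}{n_{bg} + 1} $$

with $x$ the number of null signatures reaching an equal or higher $C'$
(one-sided: only high autocorrelation is interesting) and $n_{bg}$ the
null size (default 500 per group).  Benjamini–Hochberg correction is
applied across the tested signatures; numeric meta-data and categorical
meta-data are corrected as separate families, since they are separate
analysis modes reported in separate tables.

Generating a dedicated null per signature would be wasteful, and null
distributions vary mainly with signature *size* and *sign balance*.  Input
signatures are therefore clustered by $(\log_{10}\text{size},\ \text{balance})$
with seeded k-means into (at most) 5 groups; each group gets one null at
its centre's rounded size and balance, shared by all its signatures.
When there are fewer distinct (size, balance) profiles than groups, each
profile simply becomes its own group.  For signed backgrounds the first
$\lceil \text{balance} \cdot \text{size} \rceil$ sampled genes form the
positive set.  One seed governs k-means, background sampling, and all
permutation tests in a run.

Numeric meta-data columns (library size, detection ratio, external
scores) skip the signature-score step: they are rank-transformed directly
and tested with a permutation null (default 1,000 permutations),
optionally permuting only within the levels of a grouping column — a
negative-control design that removes between-group (e.g. between-donor)
signal while preserving within-group structure.

## Categorical meta-data

Geary's C needs numeric values, so discrete variables are tested through
local label composition: for each cell the kernel-weighted count of each
label among its neighbours, $\hat c_{im} = \sum_j w_{ij} I_m(c_j)$, rows
aggregated by the centre cell's own label into a square contingency table
$X_{lm} = \sum_i \hat c_{im} I_l(c_i)$.  The table is tested with Pearson's
chi-squared ($\mathrm{dof} = (L-1)^2$) and summarized by Cramér's V,
$\sqrt{\chi^2 / (T (L-1))}$, which is 0 for well-mixed labels and 1 for
neighbourhoods purely of one label.  Two deliberate deviations from the
classical integer-count test are documented rather than "fixed": entries
are fractional (kernel weights enter as-is, unnormalized — the formulas
contain no row normalization), and observations are not independent
(each cell contributes to many neighbourhoods).  The asymptotic p-value
is therefore indicative; at single-cell sample sizes even trivial
localization is "significant", which is why results are ranked by V with
p secondary.

## Differential signature analysis

For any categorical stratification, every (signature, level) pair is
tested one-vs-all with the two-sided Wilcoxon rank-sum test.  The effect
size is the AUROC, the Mann–Whitney U rescaled to $[0,1]$, computed from
average-tie ranks so ties count half; a direction flag marks
AUROC $> 0.5$ as "up".  Exact p-values are used where `stats::wilcox.test`
provides them (small samples without ties) and the tie-corrected normal
approximation otherwise.  BH correction spans all (signature, level)
pairs of one stratification.  The same machinery applies to single-gene
rows via `differential_genes()`.

## Micro-pooling

For datasets too large to process per-cell, cells are merged into pools
of at most $P$ transcriptionally similar cells (default $P = 20$):

1. genes detected in $< 10\%$ of cells are removed, then over-dispersed
   genes are kept — Fano factor (variance/mean) above the bin median by
   more than 2 MADs, within 30 mean-expression quantile bins (constants
   exposed as arguments);
2. 20-dimensional PCA of the filtered, gene-standardized matrix (on the
   log scale the pipeline works in);
3. KNN graph ($K = \lceil\sqrt N\rceil$) and Louvain community detection,
   seeded;
4. communities larger than $P$ are split by k-means on the PCA
   coordinates with $k = \lceil S/P \rceil$, re-applied until the bound
   holds;
5. each pool's profile is the plain mean of its members' expression over
   all genes — so the size-weighted mean of pool profiles reproduces the
   global mean exactly (tested to $10^{-10}$).

Downstream analyses treat pools as cells and weight them equally; pooled
meta-data takes within-pool means (numeric) or modal labels
(categorical).  `coherence_ratios()` quantifies pool homogeneity against
an independent per-cell feature matrix (e.g. antibody counts from a
joint protein/RNA assay): the ratio of within-pool to population standard
deviation, $r = \sigma_{pool}/\sigma_{pop}$, with population $1/N$
variances; random pools give $r \approx 1$, coherent pools $r \ll 1$,
singleton pools are flagged ($r = 0$ by convention).

## Latent-component annotation

Instead of the whole graph, each latent dimension can be annotated
individually: Spearman correlation against every signature score and
numeric meta-data column (rank-based, consistent with the rest of the
package; the choice of correlation is ours — the mode's description does
not fix one), and a Kruskal–Wallis test for categorical columns.  BH is
applied within each mode.

## Synthetic data

Two seeded generators produce every test fixture:

* `simulate_clustered_dataset()` — negative-binomial counts (dispersion
  0.5, i.e. `size = 2`) with lognormal gene base means and lognormal
  library-size factors (CV 0.3); cells split evenly over clusters, donors
  assigned at random.  Planted signatures multiply the expected
  expression of a disjointly sampled gene set by $e^{\text{effect}}$ in
  the affected clusters, optionally ramped by a per-cell uniform gradient
  (planting smooth within-cluster variation).  A lognormal count noise
  mode exists as an alternative.
* `simulate_tree_dataset()` — a random milestone tree (random attachment,
  edge lengths uniform on $[1, 3]$), cells placed uniformly along edges
  with probability proportional to edge length, branch-marker genes
  ramping as $e^{\text{effect} \cdot \text{progress}}$ on their branch,
  plus a flat housekeeping signature as negative control.

The dispersion and library-size constants are fixed once as plausible
droplet-data magnitudes; they are arguments of the generator, not values
fitted to any dataset.  What the simulations *do not* contain: doublets,
ambient RNA, batch-specific gene effects, zero-inflation beyond NB,
mean-variance trends beyond a single dispersion, or realistic gene–gene
correlation outside the planted signals.  Passing tests therefore
establish correctness of the statistical machinery and calibration under
a clean generative model — not robustness to every artefact of real
droplet data.

**Problem sizes used by the validation suite** (chosen to exercise each
property at the smallest scale where it is meaningful): Geary/AUROC
oracle checks at up to 500 cells; calibration at 200 cells × 1,000
signatures; null calibration at 500 cells × 500 signatures with 500
backgrounds per group; power at 20 replicates of 1,000 cells (two
500-cell clusters, +1 natural-log-unit effect on 50 genes, 500
backgrounds); K-stability at 1,000 cells; micro-pooling consistency at
5,000 cells with three planted gradients and $P = 20$; trajectories at
200 cells on 7-milestone trees.

## Known limitations

* The chi-squared p-value for categorical variables inherits the
  fractional-count and dependence caveats above; V is the quantity to
  rank by.
* Weights are evaluated over directed neighbour pairs only; no
  symmetrized variant is provided.
* Micro-pooling is undefined for trajectory inputs (pooling would need
  pooled positions on the tree); the pipeline rejects the combination.
* The analytic score correction assumes the gene universe is large
  relative to the signature; for signatures comprising a large fraction
  of the universe the corrected variance is noticeably below 1.
* Approximate nearest-neighbour search is not implemented; very large
  datasets should be micro-pooled first, which is the intended workflow.
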