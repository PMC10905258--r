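---
title: "Batch-effect evaluation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-effect evaluation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batcheval)
```

## The problem

Merging expression datasets from several runs, tissue sections or platforms
introduces systematic technical variation — batch effects — that is easily
mistaken for biology. `batcheval` asks two questions of a merged dataset:
how strongly do the batches separate (mixing), and how much of the
biological structure (cell/domain types) survives the integration
(preservation)? It answers with a statistical test battery, a neural domain
classifier, neighborhood-mixing metrics, and a composite score, for the raw
integration and for any registered correction method.

## Preprocessing and embeddings

Counts are normalized by global min–max rescaling followed by `log1p`:

$$\hat x = \log\!\left(1 + \frac{x - x_{\min}}{x_{\max} - x_{\min}}\right)$$

with the extrema taken over the **entire merged matrix**, not per gene.
Per-gene scaling would re-standardize each batch's dynamic range and erase
exactly the cross-batch depth differences the tool is trying to measure;
global scaling keeps observations comparable while bounding values in
$[0, \log 2]$. A constant matrix (zero range) normalizes to all zeros with
a warning rather than an error, so degenerate fixtures flow through.

All quantitative metrics operate in PCA space (default 50 components,
exact SVD via `prcomp`, component signs fixed so the largest-magnitude
loading is positive — making the embedding reproducible bit-for-bit). UMAP
(15 neighbors, seeded, single-threaded) is computed for display panels
only: its neighborhood distortions would contaminate composition-based
metrics like k-BET and LISI, so it is deliberately excluded from scoring.

Neighbor graphs are exact Euclidean k-NN with self excluded and distance
ties broken toward the lower observation index, so a graph is a pure
function of its embedding. Brute-force distances are acceptable because the
graph sizes the metrics need stay desk-scale.

## The statistical battery

The tested quantity throughout is the per-observation **total count**
(library size), grouped by batch: it is the observable most directly
affected by platform and depth differences, and pairwise pooled sample
sizes then add up to the summed batch sizes, as they should.

- One-way ANOVA *F* with the critical value $F_{\mathrm{ref}}$ at
  $1-\alpha$ (default $\alpha = 0.05$) and df $(k-1, N-k)$ printed beside
  it, so a reader can compare statistic and reference directly.
- Kruskal–Wallis $H$ with average ranks for ties and the standard
  correction divisor $1 - \sum(t^3 - t)/(N^3 - N)$, referred to
  $\chi^2_{k-1}$. (Rank-sum methods are sometimes described loosely in
  terms of t-statistics; the implemented statistic is the classical $H$.)
  An all-constant input defines $H = 0$, $p = 1$.
- Pairwise two-sample Kolmogorov–Smirnov statistics with asymptotic
  two-sided p-values; count totals tie frequently, so the exact-p tie
  warning is suppressed by design.
- A condition × batch contingency table summarized by Pearson's $\chi^2$
  (no continuity correction), the contingency coefficient
  $C = \sqrt{\chi^2/(\chi^2+N)}$ and Cramér's
  $V = \sqrt{\chi^2/(N(k-1))}$, $k$ the smaller table dimension. When no
  condition column exists, totals are binned into quartiles as a proxy
  condition and the report says so; the association then measures how
  strongly library size tracks batch.

## The domain classifier

Batch separability is estimated by a classifier predicting the batch from
each observation's feature vector: one relu hidden layer (default 128
units) with a linear softmax head over the $k$ batches. A relu unit alone
cannot emit class probabilities, so the softmax head is the minimal
completion that makes the focal loss well defined. Training uses minibatch
SGD (learning rate 0.01, batch size 64, 100 epochs) on the focal loss

$$\mathcal L = -\alpha\,(1 - P_t)^\gamma \log P_t,$$

defaulting to $\alpha = 1$, $\gamma = 2$ — the conventional focal setting,
which down-weights easy examples so unbalanced batches do not dominate; it
reduces exactly to cross-entropy at $\gamma = 0$ (asserted in the tests,
along with a numerical check of the analytic gradient). Features are
standardized with training-split statistics before training: raw PCA
scores have arbitrary magnitude and would saturate the softmax at
initialization, exploding the focal gradient. Probabilities are clamped at
$10^{-12}$; a non-finite epoch loss aborts with diagnostics rather than
returning garbage.

The split is stratified by batch with training size exactly
$\lfloor 0.7 N \rfloor$: per-batch quotas $\lfloor 0.7 n_i \rfloor$ plus a
largest-remainder top-up, deterministic given the seed. Held-out accuracy
is DomainAcc; the **accept rate** is $1 - \mathrm{DomainAcc}$, so the
quantity entering the composite score is high when batches are
indistinguishable. For the raw variant the classifier sees the normalized
gene vectors by default (a `pca` option trades fidelity for speed);
corrected variants are always classified in their own output embedding,
since their corrected gene space may not exist.

## Mixing and preservation metrics

**k-BET.** For each tested observation, the composition of its $k = 25$
nearest neighbors is compared with the global batch frequencies $f$ by
$\kappa_j^k = \sum_i (n_{ji}^k - f_i k)^2/(f_i k) \sim \chi^2_{l-1}$.
A neighborhood is accepted at $p > 0.05$. With many observations only a
10% subsample (at least 100 neighborhoods, seeded) is tested. Reported:
mean $\kappa$, mean p-value, accepted and rejected fractions. Batches
absent from the data are dropped from the degrees of freedom.

**LISI.** The inverse Simpson index $1/\sum p^2$ of the label proportions
in each observation's neighborhood (itself plus its $k = 90$ nearest
neighbors, uniform weights — simpler and more directly testable than
perplexity-weighted kernels). Raw values lie in $[1, \#\text{labels}]$;
each label set's per-observation vector is min–max normalized to $[0,1]$
and averaged (a constant vector normalizes to zeros). Batch labels give
iLISI (higher = better mixing), type labels give cLISI (lower = better
preservation); the F1 combiner is
$2(1-\text{cLISI})\,\text{iLISI} / ((1-\text{cLISI})+\text{iLISI})$, with
0 returned on a vanishing denominator.

**Silhouette.** Mean silhouette width (Euclidean, full pairwise, via
`cluster::silhouette`) under batch labels (iSS) and type labels (cSS),
with a seeded subsample above 10,000 observations to keep the $O(N^2)$
distance matrix tractable. Two F1 conventions are exposed:

- `table_consistent` (default): $2(1-iSS)\,cSS/((1-iSS)+cSS)$ on the raw
  means clipped to $[0,1]$. This is the arithmetic that reproduces the
  published summary tables of this metric family.
- `equation_9`: first rescale $s' = (1+s)/2$ and combine the primed
  values. As printed, this formula does **not** reproduce those same
  published tables (at the reference inputs it yields 0.2757 versus the
  tabulated 0.4318), so it is treated as an erratum: available, documented,
  not default.

When no cell-type annotation exists, Leiden clustering (resolution 1.0,
seeded) of the symmetrized PCA k-NN graph supplies fallback type labels,
and the report marks type-based scores as cluster-based.

**Composite.** The BatchEval score is the unweighted mean of F1\_LISI,
F1\_SS and the classifier accept rate — three views (local composition,
global geometry, decision-boundary separability) given equal weight. All
components lie in $[0,1]$ by construction.

## Benchmarking and recommendation

Each registered correction method maps the dataset to either a corrected
embedding or a corrected expression matrix (re-embedded by PCA); every
variant, raw included, is then evaluated with identical seeds so
differences are attributable to the method alone. A raw composite score
below 0.5 triggers the "has batch effect, requires further processing"
conclusion and the argmax-scoring correction is recommended (ties broken
alphabetically); the 0.5 cutoff is the natural midpoint of the score's
range, chosen because published examples attach that conclusion to raw
scores far below one half. Methods that fail are recorded and skipped;
optional external tools register adapters only when their packages are
installed. The built-in baseline — per-batch standardization of PCA scores
— is a deliberately simple location/scale correction that keeps the
benchmark loop exercisable with no extra dependencies.

## The synthetic generator

`simulate_batches()` draws counts from a negative binomial with mean

$$\mu_{gcb} = \text{base}_g \cdot \text{type}_{g,t(c)} \cdot
\text{batch}_{gb} \cdot \text{lib}_c,$$

log-normal gene baselines, type-marker genes scaled by
$e^{\text{type\_effect}}$, per-(gene, batch) factors
$\log \text{batch}_{gb} \sim N(0, \text{batch\_effect}^2)$, log-normal
per-cell library sizes, and an optional per-batch depth multiplier drawn
from `libsize_factor`. Defaults: 3 batches × 300 cells × 500 genes (large
enough for stable neighborhood statistics, small enough to regenerate in
seconds), 3 shared cell types, 30% marker genes at `type_effect = 2`
(clean-data type silhouette around 0.3, matching what well-annotated real
datasets show in PCA space), `batch_effect = 1` (a clearly detectable but
not degenerate effect), dispersion 2, and a **degenerate** depth range
`c(1, 1)` so that `batch_effect = 0` produces genuinely exchangeable
batches — the null condition several tests rely on. Depth differences are
opt-in via `libsize_factor`.

What it emulates: multiplicative per-gene batch distortions, depth
differences, shared cell types, overdispersed counts. What it does not:
spatial expression patterns (coordinates, when requested, are uniform
noise), batch-specific cell-type composition shifts, ambient RNA, doublets
or dropout beyond NB sampling. Passing tests therefore demonstrate correct
behavior under multiplicative batch distortion of otherwise exchangeable
data, not robustness to every artifact of real experiments.

One structural limitation is worth stating: because the generator's batch
factors are independent per gene, increasing `batch_effect` inflates
cross-batch within-type distances without bound while the between-type
contrast stays fixed, so the type silhouette cSS necessarily decays toward
zero as the batch effect grows (it is ~0.3 with no batch effect and
effectively gone by `batch_effect = 2`). Type-label recoverability is
therefore only asserted up to moderate batch effects; at strong ones, no
embedding-space metric could recover it from these data, which is itself a
realistic property of severely confounded integrations.

## Numerical and reproducibility choices

- One global seed fans out to per-module seeds by fixed offsets
  (`derive_seed`), all below $2^{31}$; identical configurations reproduce
  every score bit-for-bit (asserted in the tests).
- Gene-wise variance is the population variance (denominator $N$): it is
  purely descriptive (mean–variance panel), not an inferential estimate.
- k-NN ties resolve to the lower index; PCA signs are fixed; stratified
  splits use largest-remainder rounding with ties to the earlier batch
  level — every tie-break is deterministic and documented at the function.
- Reports round to 4 decimals for display; the JSON sidecar keeps full
  precision, and the export/import round trip is tested.
- The silhouette subsample cap (10,000), k-BET subsample floor (100
  neighborhoods) and scatter-panel cap (50,000 points) bound memory and
  file sizes without materially changing the statistics at those scales.

## Known limitations

- Correction methods are compared in their own output spaces; scores are
  comparable as "quality of the space each method hands downstream", not
  as measurements in one common space.
- The contingency analysis with the quartile proxy condition largely
  restates the library-size/batch association; it becomes informative when
  a genuine experimental-condition column is supplied.
- The classifier is intentionally small and fully deterministic; it
  measures linear-plus-one-hidden-layer separability, not the ceiling of
  what a deep model could detect.
- h5ad input requires a Python with `anndata` on the PATH (the file is
  converted in a subprocess); CSV and MTX need nothing beyond R.
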