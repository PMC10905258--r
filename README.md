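# batcheval

Batch-effect evaluation for multi-dataset transcriptomics integration.

When several single-cell or spatially resolved transcriptomics datasets
(different runs, sections, platforms) are merged for joint analysis,
technical batch effects can masquerade as biology. `batcheval` quantifies
how severe the batch effect in a merged dataset is, benchmarks candidate
batch-correction methods, and renders an offline HTML report with a
recommendation. It is aimed at analysts deciding *whether* a merged dataset
needs correction and *which* correction to use, before any downstream
analysis.

## What it computes

For a merged observations × genes count matrix with a batch label per
observation (spot/cell), the package runs:

- **Statistical battery** on per-observation total counts: one-way ANOVA
  *F* with its critical value *F*ref(k−1, N−k), the Kruskal–Wallis statistic

  H = 12/(N(N+1)) Σᵢ Rᵢ²/nᵢ − 3(N+1)   (tie-corrected),

  pairwise two-sample Kolmogorov–Smirnov tests
  stat = supₓ|F₁(x) − F₂(x)|, and the association between an
  experimental-condition label and batch via Cramér's V
  φc = √(χ²/(N(k−1))).
- **Domain classifier**: a one-hidden-layer relu network predicting the
  batch from each observation's expression vector, trained with the focal
  loss −α(1−Pₜ)^γ log(Pₜ) by minibatch SGD on a stratified 70/30 split.
  Its held-out accuracy (DomainAcc) measures batch separability; the
  *accept rate* 1 − DomainAcc is high when batches are indistinguishable.
- **Neighborhood mixing and biology preservation** in PCA space:
  k-BET (per-neighborhood chi-square κⱼᵏ = Σᵢ (nⱼᵢᵏ − fᵢk)²/(fᵢk) against
  the global batch frequencies, summarized by the accepted fraction at
  α = 0.05), the local inverse Simpson index under batch labels (iLISI)
  and cell-type labels (cLISI) with their F1 combiner

  F1_LISI = 2(1−cLISI)·iLISI / ((1−cLISI)+iLISI),

  and mean silhouettes under batch (iSS) and type (cSS) labels with their
  F1 combiner (two conventions exposed; see the methods vignette).
- **Composite score**: BatchEval score = mean(F1_LISI, F1_SS, accept rate),
  in [0, 1]; higher means better-mixed and biology-preserving. The raw
  integration and every correction method are scored identically and the
  best-scoring correction is recommended when the raw score falls below
  0.5.

Inputs: dense CSV/TSV, MatrixMarket MTX trios, or AnnData h5ad. A seeded
negative-binomial simulator with controllable batch effect, shared cell
types and library-size differences makes every stage runnable without
external data.

## Worked example

```r
library(batcheval)

ds <- simulate_batches(sim_config(batch_effect = 1, seed = 1))
ds
#> IntegratedDataset: 900 observations x 500 genes
#>   batches: batch0 (300), batch1 (300), batch2 (300)
#>   cell types: 3

ds <- normalize_dataset(ds)          # global min-max + log1p
ds <- pca_embed(ds, n_components = 50)
summary <- run_benchmark(ds, methods = "baseline")
summary
#> BenchmarkSummary ( 2 variants )
#>                    Raw baseline
#> k-BET score     0.0000   0.1700
#> 95% p value     0.0000   0.0482
#> BatchEval score 0.1712   0.2878
#> This dataset has batch effect and requires further processing. Recommend to use "baseline".
```

Reading the output: the simulated batch effect (per-gene log-normal shifts
of sd 1) makes the raw integration fail k-BET everywhere (accepted
fraction 0.0000 — no neighborhood has the global batch composition) and
drives the composite score down to 0.1712, far below the 0.5 threshold, so
correction is advised. The built-in baseline (per-batch centering/scaling
of the PCA scores) improves mixing (k-BET 0.17, score 0.2878) and, being
the only registered method here, is recommended. A full run with report:

```r
run_pipeline(ds, methods = "baseline", outdir = "report")
# report/index.html, report/raw.html, report/method_baseline.html,
# report/metrics.json, report/manifest.json
```

A thin CLI wraps the same functions
(`Rscript inst/cli/batcheval.R run --inputs a.csv,b.csv --batch-key batch
--methods baseline --outdir report --seed 0`, plus `simulate`, `metrics`
and `report` subcommands).

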