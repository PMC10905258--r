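# Shared fixture builders; everything is generated in code at test time.

# Tiny deterministic dataset: two batches of Gaussian-ish counts with an
# optional mean shift on the second batch.
make_toy_ds <- function(n_per_batch = 20, n_genes = 10, shift = 0, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_batch
  m <- matrix(rpois(n * n_genes, lambda = 5), n, n_genes)
  m[(n_per_batch + 1):n, ] <- m[(n_per_batch + 1):n, ] + shift
  IntegratedDataset(m, batch = rep(c("a", "b"), each = n_per_batch),
                    cell_type = rep(c("t1", "t2"), n_per_batch))
}

# Hand-built neighbor graph (for fabricated neighborhood compositions).
make_graph <- function(indices) {
  structure(list(indices = indices, k = ncol(indices), metric = "euclidean",
                 embedding = "manual"),
            class = "NeighborGraph")
}

# Small simulated dataset with normalized layer and PCA attached.
make_sim_ds <- function(batch_effect = 1.0, seed = 1, cells_per_batch = 150,
                        n_genes = 300, ...) {
  ds <- simulate_batches(sim_config(batch_effect = batch_effect, seed = seed,
                                    cells_per_batch = cells_per_batch,
                                    n_genes = n_genes, ...))
  ds <- normalize_dataset(ds)
  pca_embed(ds, n_components = 30)
}

# Fast evaluation config for small fixtures.
fast_config <- function(seed = 0) {
  batcheval_config(
    classifier = classifier_config(hidden_units = 32, epochs = 40, seed = seed),
    classifier_features = "pca", pca_components = 30, lisi_k = 30,
    kbet_k = 15, seed = seed)
}

# Fabricated benchmark summary with given composite scores (for the
# recommendation logic, which only reads scores).
make_summary <- function(scores) {
  variants <- lapply(scores, function(s) list(score = list(batcheval = s)))
  structure(list(variants = variants, failed = list(),
                 table = data.frame(), types_source = "cell_type",
                 recommended = NULL, conclusion = NULL),
            class = "BenchmarkSummary")
}
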