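test_that("min-max log normalization matches hand values and its bounds", {
  m <- matrix(c(0, 5, 10), 3, 1)
  out <- minmax_log_normalize(m)
  expect_equal(as.numeric(out), c(0, log1p(0.5), log1p(1)))
  expect_equal(out[3], log(2), tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(3)
  x <- matrix(rexp(200, 0.1), 20, 10)
  y <- minmax_log_normalize(x)
  expect_true(all(y >= 0 & y <= log(2)))
  # monotone in x: ordering of entries is preserved
  expect_equal(order(as.numeric(x)), order(as.numeric(y)))

  expect_warning(z <- minmax_log_normalize(matrix(7, 2, 2)), "constant")
  expect_equal(z, matrix(0, 2, 2))
  expect_error(minmax_log_normalize(matrix(c(-1, 1), 1, 2)), "non-negative")
})

test_that("per-observation totals are row sums, invariant to gene order", {
  ds <- IntegratedDataset(matrix(c(1, 3, 2, 4), 2, 2), batch = c("a", "a"))
  expect_equal(per_cell_total_counts(ds), c(3, 7))
  ds0 <- IntegratedDataset(rbind(c(0, 0), c(1, 2)), batch = c("a", "a"))
  expect_equal(per_cell_total_counts(ds0), c(0, 3))

  ds1 <- make_toy_ds()
  perm <- sample(ncol(ds1$matrix))
  ds2 <- IntegratedDataset(as.matrix(ds1$matrix)[, perm], batch = ds1$batch)
  expect_equal(per_cell_total_counts(ds2), per_cell_total_counts(ds1))
})

test_that("gene mean/variance uses the population variance, per batch", {
  ds <- IntegratedDataset(matrix(c(2, 2, 2, 0, 2, 4), 3, 2), batch = rep("a", 3))
  mv <- per_gene_mean_variance(ds)
  expect_equal(mv$mean, c(2, 2))
  expect_equal(mv$variance, c(0, 8 / 3))  # ddof 0

  ds2 <- IntegratedDataset(matrix(c(0, 2), 2, 1), batch = rep("a", 2))
  mv2 <- per_gene_mean_variance(ds2)
  expect_equal(mv2$mean, 1)
  expect_equal(mv2$variance, 1)

  # shifting one batch by a constant moves means, not variances
  base <- make_toy_ds(shift = 0)
  shifted <- make_toy_ds(shift = 7)
  a <- per_gene_mean_variance(base, by_batch = TRUE)
  b <- per_gene_mean_variance(shifted, by_batch = TRUE)
  sel <- a$batch == "b"
  expect_equal(b$mean[sel], a$mean[sel] + 7)
  expect_equal(b$variance[sel], a$variance[sel])
})

test_that("PCA embedding is deterministic with a fixed sign convention", {
  # rank-1 matrix: one component carries all the variance
  u <- 1:12
  ds <- IntegratedDataset(outer(u, c(1, 2, 3)), batch = rep("a", 12))
  ds <- normalize_dataset(ds)
  ds <- pca_embed(ds, n_components = 2)
  sdev <- attr(ds$embeddings$pca, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.999)

  # duplicated observations get identical scores
  m <- as.matrix(make_toy_ds()$matrix)
  dup <- IntegratedDataset(rbind(m, m[1, , drop = FALSE]), batch = rep("a", nrow(m) + 1))
  dup <- pca_embed(normalize_dataset(dup), n_components = 3)
  expect_equal(dup$embeddings$pca[nrow(m) + 1, ], dup$embeddings$pca[1, ],
               ignore_attr = TRUE)

  ds1 <- pca_embed(normalize_dataset(make_toy_ds()), n_components = 4, seed = 0)
  ds2 <- pca_embed(normalize_dataset(make_toy_ds()), n_components = 4, seed = 0)
  expect_identical(ds1$embeddings$pca, ds2$embeddings$pca)

  expect_error(pca_embed(normalize_dataset(make_toy_ds(n_genes = 3)), n_components = 3),
               "n_components")
  expect_error(pca_embed(make_toy_ds()), "normalized layer")
})

test_that("UMAP is seeded, bounded by N, and preserves blob separation", {
  set.seed(5)
  n <- 60
  blob <- rbind(matrix(rnorm(n * 5), n, 5), matrix(rnorm(n * 5, mean = 30), n, 5))
  counts <- abs(blob) + 1
  ds <- IntegratedDataset(counts, batch = rep(c("a", "b"), each = n))
  ds <- normalize_dataset(ds)
  ds$embeddings$pca <- blob  # embed the raw blob geometry
  ds1 <- umap_embed(ds, n_neighbors = 10, seed = 3)
  ds2 <- umap_embed(ds, n_neighbors = 10, seed = 3)
  expect_identical(ds1$embeddings$umap, ds2$embeddings$umap)

  um <- ds1$embeddings$umap
  lab <- rep(c(1, 2), each = n)
  cent <- rbind(colMeans(um[lab == 1, ]), colMeans(um[lab == 2, ]))
  pred <- apply(um, 1, function(p) which.min(colSums((t(cent) - p)^2)))
  expect_gt(mean(pred == lab), 0.95)

  small <- make_toy_ds(n_per_batch = 5)
  small <- pca_embed(normalize_dataset(small), n_components = 3)
  expect_error(umap_embed(small, n_neighbors = 50), "too few")
})

test_that("exact kNN handles hand cases, ties, and matches brute force", {
  ds <- IntegratedDataset(matrix(c(0, 1, 10, 1, 1, 1), 3, 2), batch = rep("a", 3))
  ds$embeddings$pca <- matrix(c(0, 1, 10), 3, 1)
  g <- knn_neighbors(ds, "pca", k = 1)
  expect_equal(as.integer(g$indices), c(2L, 1L, 2L))
  expect_error(knn_neighbors(ds, "nope", 1), "unknown embedding")

  # equidistant neighbors resolve to the lower index
  tie <- knn_from_matrix(matrix(c(0, -1, 1), 3, 1), k = 1)
  expect_equal(tie$indices[1, ], 2L)

  # k = N - 1 gives every other point
  full <- knn_from_matrix(matrix(rnorm(10), 5, 2), k = 4)
  for (i in 1:5) expect_setequal(full$indices[i, ], setdiff(1:5, i))

  # oracle: all-pairs scan on 200 points
  set.seed(11)
  x <- matrix(rnorm(200 * 3), 200, 3)
  k <- 7
  g <- knn_from_matrix(x, k)
  expect_equal(dim(g$indices), c(200L, k))
  for (i in c(1, 50, 113, 200)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    expect_equal(g$indices[i, ], order(d)[1:k])
  }
})
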