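test_that("dataset invariants are enforced", {
  m <- matrix(1:12, 4, 3)
  ds <- IntegratedDataset(m, batch = c("a", "a", "b", "b"))
  expect_s3_class(ds, "IntegratedDataset")
  expect_equal(n_obs(ds), 4)
  expect_equal(unname(batch_sizes(ds)), c(2L, 2L))

  expect_error(IntegratedDataset(m, batch = c("a", "b")), "batch labels")
  expect_error(IntegratedDataset(-m, batch = rep("a", 4)), "non-negative")
  mneg <- m; mneg[1] <- NA
  expect_error(IntegratedDataset(mneg, batch = rep("a", 4)), "non-negative and finite")
  bad <- ds; bad$embeddings$pca <- matrix(0, 3, 2)
  expect_error(validate_dataset(bad), "embedding")
})

test_that("CSV round trip preserves counts, labels and dimensions", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = paste0("c", 1:4),
                   g1 = c(1, 0, 2, 3), g2 = c(4, 5, 0, 1), g3 = c(2, 2, 2, 2),
                   b = c("x", "x", "y", "y"))
  write.csv(df, path, row.names = FALSE)
  ds <- load_dataset(path, format = "csv", batch_key = "b")
  expect_equal(n_obs(ds), 4)
  expect_equal(ds$gene_ids, c("g1", "g2", "g3"))
  expect_equal(unname(as.matrix(ds$matrix)[, "g2"]), c(4, 5, 0, 1))
  expect_equal(as.character(ds$batch), c("x", "x", "y", "y"))
})

test_that("missing batch column errors name the available columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "c1", g1 = 1, g2 = 2), path, row.names = FALSE)
  expect_error(load_dataset(path, format = "csv", batch_key = "nope"),
               "g1, g2")
  expect_error(load_dataset(path, format = "csv"), "batch_key")
  expect_error(load_dataset("no/such/file.csv", format = "csv", batch_key = "b"),
               "not found")
})

test_that("MTX trio loads with observation count and values preserved", {
  dir <- withr::local_tempdir()
  set.seed(1)
  m <- Matrix::rsparsematrix(7, 10, density = 0.4)  # genes x cells on disk
  m@x <- abs(m@x)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(paste0("bc", 1:10), file.path(dir, "barcodes.tsv"))
  writeLines(paste0("g", 1:7), file.path(dir, "features.tsv"))
  ds <- load_dataset(dir, format = "mtx", batch = "b0")
  expect_equal(n_obs(ds), 10)
  expect_equal(ds$gene_ids, paste0("g", 1:7))
  expect_equal(as.matrix(ds$matrix), t(as.matrix(m)), ignore_attr = TRUE)
  expect_equal(nlevels(ds$batch), 1)
})

test_that("h5ad files load through the anndata converter", {
  dir <- withr::local_tempdir()
  h5 <- file.path(dir, "toy.h5ad")
  code <- paste(
    "import sys, numpy as np, anndata, pandas as pd",
    "X = np.arange(12).reshape(4, 3).astype(float)",
    "obs = pd.DataFrame({'batch': ['a','a','b','b'], 'ct': ['t1','t2','t1','t2']}, index=[f'c{i}' for i in range(4)])",
    "ad = anndata.AnnData(X=X, obs=obs)",
    "ad.var_names = ['g1','g2','g3']",
    "ad.write_h5ad(sys.argv[1])", sep = "; ")
  status <- system2("python", c("-c", shQuote(code), shQuote(h5)),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ds <- load_dataset(h5, format = "h5ad", batch_key = "batch", celltype_key = "ct")
  expect_equal(n_obs(ds), 4)
  expect_equal(as.character(ds$batch), c("a", "a", "b", "b"))
  expect_equal(as.character(ds$cell_type), c("t1", "t2", "t1", "t2"))
  expect_equal(unname(as.matrix(ds$matrix)[2, ]), c(3, 4, 5))
})

make_named_ds <- function(genes, n = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * length(genes), 5), n, length(genes))
  colnames(m) <- genes
  IntegratedDataset(m, batch = rep("b", n), gene_ids = genes)
}

test_that("merging honors the gene policy and is order-insensitive", {
  d1 <- make_named_ds(c("A", "B", "C"))
  d2 <- make_named_ds(c("B", "C", "D"), seed = 2)
  mi <- merge_datasets(list(d1, d2), "intersection", batch_names = c("b0", "b1"))
  expect_setequal(mi$gene_ids, c("B", "C"))
  mu <- merge_datasets(list(d1, d2), "union_zero_fill", batch_names = c("b0", "b1"))
  expect_setequal(mu$gene_ids, c("A", "B", "C", "D"))
  # absent genes are zero-filled
  expect_true(all(as.matrix(mu$matrix)[mu$batch == "b1", "A"] == 0))
  expect_true(all(as.matrix(mu$matrix)[mu$batch == "b0", "D"] == 0))
  # order insensitivity of the produced gene set
  rev_i <- merge_datasets(list(d2, d1), "intersection", batch_names = c("b1", "b0"))
  expect_setequal(rev_i$gene_ids, mi$gene_ids)

  d3 <- make_named_ds(c("X", "Y"))
  expect_error(merge_datasets(list(d1, d3), "intersection", batch_names = c("b0", "b1")),
               "empty gene intersection")
  expect_error(merge_datasets(list(d1, d2), batch_names = c("b0", "b0")),
               "duplicate")
  expect_error(merge_datasets(list(d1)), "at least two")
})

test_that("self-merge doubles N, keeps batch sizes, and deduplicates ids", {
  d <- make_toy_ds(n_per_batch = 5)
  single <- IntegratedDataset(as.matrix(d$matrix), batch = rep("s", n_obs(d)),
                              gene_ids = d$gene_ids)
  m <- merge_datasets(list(single, single), batch_names = c("b0", "b1"))
  expect_equal(n_obs(m), 2 * n_obs(single))
  expect_equal(unname(batch_sizes(m)), rep(n_obs(single), 2))
  expect_equal(nlevels(m$batch), 2)
  expect_false(anyDuplicated(m$obs_ids) > 0)
  expect_equal(ncol(m$matrix), ncol(single$matrix))
})

test_that("metrics export is a faithful full-precision round trip", {
  ds <- make_sim_ds()
  s <- run_benchmark(ds, methods = "baseline", config = fast_config())
  path <- withr::local_tempfile(fileext = ".json")
  export_metrics(s, path)
  m <- import_metrics(path)
  expect_setequal(names(m$variants), c("Raw", "baseline"))
  # full precision (far beyond the 4-decimal display rounding)
  expect_equal(m$variants$Raw$batcheval, s$variants$Raw$score$batcheval,
               tolerance = 1e-12)
  expect_identical(m$variants$baseline$kbet$accept_rate,
                   s$variants$baseline$kbet$accept_rate)
  expect_equal(m$variants$Raw$lisi$iLISI, s$variants$Raw$lisi$iLISI,
               tolerance = 1e-12)
  expect_identical(m$conclusion, s$conclusion)
})
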