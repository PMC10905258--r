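test_that("k-BET reproduces hand chi-square values on fabricated neighborhoods", {
  # 20 observations, balanced two batches; every neighborhood drawn entirely
  # from batch a: counts (10, 0) against expectation (5, 5) -> kappa = 10
  batch <- rep(c("a", "b"), each = 10)
  idx <- matrix(rep(1:10, times = 20), 20, 10, byrow = TRUE)
  g <- make_graph(idx)
  res <- kbet(g, batch, alpha = 0.05)
  expect_equal(res$chi_mean, 10)
  expect_equal(res$p_summary, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(res$p_summary, 0.001565402, tolerance = 1e-6)
  expect_equal(res$accept_rate, 0)
  expect_equal(res$reject_rate, 1)

  # neighborhoods matching the global frequencies exactly: kappa = 0, p = 1
  null_idx <- matrix(rep(c(1:5, 11:15), times = 20), 20, 10, byrow = TRUE)
  null_res <- kbet(make_graph(null_idx), batch)
  expect_equal(null_res$chi_mean, 0)
  expect_equal(null_res$accept_rate, 1)
})

test_that("k-BET kappa equals an independent chi-square on raw count tables", {
  set.seed(13)
  n <- 90
  emb <- matrix(rnorm(n * 4), n, 4)
  batch <- factor(sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  g <- knn_from_matrix(emb, k = 12)
  res <- kbet(g, batch, sample_fraction = 1, seed = 0)
  f <- as.numeric(table(batch)) / n
  for (ii in seq_along(res$tested)) {
    j <- res$tested[ii]
    counts <- table(factor(batch[g$indices[j, ]], levels = levels(batch)))
    oracle <- suppressWarnings(chisq.test(as.numeric(counts), p = f))
    expect_equal(res$kappa[ii], unname(oracle$statistic), tolerance = 1e-10)
  }
})

test_that("random batch labels on a random embedding are mostly accepted", {
  set.seed(17)
  n <- 500
  emb <- matrix(rnorm(n * 5), n, 5)
  batch <- sample(c("a", "b"), n, replace = TRUE)
  g <- knn_from_matrix(emb, k = 25)
  res <- kbet(g, batch, alpha = 0.05, sample_fraction = 1, seed = 0)
  expect_gte(res$accept_rate, 0.85)
})

test_that("inverse Simpson neighborhoods match hand proportions", {
  # k = 1, neighbor from the other batch: proportions (0.5, 0.5) -> raw 2
  g1 <- make_graph(matrix(c(2L, 1L), 2, 1))
  expect_equal(batcheval:::inverse_simpson(g1, c("a", "b")), c(2, 2))
  # all neighbors (and self) share one label -> raw 1 (minimum)
  expect_equal(batcheval:::inverse_simpson(g1, c("a", "a")), c(1, 1))
  # uniform over B labels -> raw B (maximum)
  gB <- make_graph(matrix(c(2L, 3L, 1L, 3L, 1L, 2L), 3, 2, byrow = TRUE))
  expect_equal(batcheval:::inverse_simpson(gB, c("x", "y", "z")), c(3, 3, 3))
})

test_that("LISI normalization maps mixed high and separated low", {
  set.seed(19)
  # two separated blobs, batch == blob: raw iLISI 1 everywhere -> normalized 0
  emb <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 20), 50, 2))
  batch_sep <- rep(c("a", "b"), each = 50)
  g <- knn_from_matrix(emb, 10)
  sep <- lisi_scores(g, batch_sep, batch_sep)
  expect_true(all(sep$raw_ilisi == 1))
  expect_equal(sep$iLISI, 0)

  # random labels on one blob: most neighborhoods near-balanced
  one <- matrix(rnorm(400), 200, 2)
  gl <- knn_from_matrix(one, 20)
  mixed <- lisi_scores(gl, sample(c("a", "b"), 200, TRUE), batch_sep[1:200])
  expect_gt(mean(mixed$raw_ilisi), 1.7)
  expect_warning(one_lvl <- lisi_scores(gl, rep("a", 200), batch_sep[1:200]),
                 "single level")
  expect_equal(one_lvl$iLISI, 0)
})

test_that("LISI F1 combiner follows the harmonic form with a safe denominator", {
  expect_equal(f1_lisi(0, 0.5), 0)
  expect_equal(f1_lisi(1, 0), 1)
  expect_equal(f1_lisi(0, 1), 0)  # zero denominator guard
  expect_equal(f1_lisi(0.5, 0.5), 2 * 0.5 * 0.5 / 1)
  expect_error(f1_lisi(1.2, 0), ">= 0|<= 1")
})

test_that("silhouette scores match hand geometry and random-label nulls", {
  emb <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c("a", "a", "b", "b")
  res <- silhouette_scores(emb, lab, lab)
  # point at 0: a = 0.1, b = (10 + 10.1)/2 -> s = (10.05 - 0.1)/10.05
  expect_gt(res$iSS, 0.95)
  expect_equal(res$iSS, res$cSS)
  expect_equal(res$iSS_prime, (1 + res$iSS) / 2)

  set.seed(23)
  blob <- matrix(rnorm(300), 150, 2)
  rnd <- silhouette_scores(blob, sample(c("a", "b"), 150, TRUE), rep(c("x", "y"), 75))
  expect_lt(abs(rnd$iSS), 0.1)
  expect_true(res$iSS >= -1 && res$iSS <= 1)
  expect_warning(one <- silhouette_scores(blob, rep("a", 150), rep(c("x", "y"), 75)),
                 "single level")
  expect_equal(one$iSS, 0)

  # subsampling is seeded and keeps the score close to the full computation
  big <- rbind(matrix(rnorm(600), 300, 2), matrix(rnorm(600, 8), 300, 2))
  biglab <- rep(c("a", "b"), each = 300)
  sub <- silhouette_scores(big, biglab, biglab, max_n = 200, seed = 1)
  full <- silhouette_scores(big, biglab, biglab)
  expect_equal(sub$iSS, full$iSS, tolerance = 0.05)
  expect_identical(sub$iSS, silhouette_scores(big, biglab, biglab, max_n = 200, seed = 1)$iSS)
})

test_that("silhouette F1 agrees with both published conventions", {
  # printed-table arithmetic on the raw means
  expect_lt(abs(f1_ss(0.7842, 0.4911) - 0.2999), 2e-4)
  # primed rescaling changes the answer
  ip <- (1 + 0.6675) / 2; cp <- (1 + 0.6155) / 2
  expect_equal(f1_ss(0.6675, 0.6155, mode = "equation_9"),
               2 * (1 - ip) * cp / ((1 - ip) + cp))
  # negative silhouettes clip to zero in table-consistent mode
  expect_equal(f1_ss(-0.5, -0.2), 0)
  expect_equal(f1_ss(1, 0), 0)  # zero numerator/denominator guard
})

test_that("composite score is the exact mean of its three components", {
  s <- batcheval_score(0.2, 0.4, 0.6)
  expect_equal(s$batcheval, (0.2 + 0.4 + 0.6) / 3)
  expect_equal(batcheval_score(1, 1, 1)$batcheval, 1)
  expect_equal(batcheval_score(0, 0, 0)$batcheval, 0)
  expect_error(batcheval_score(1.5, 0, 0), ">= 0|<= 1")
})

test_that("fallback Leiden clusters recover well-separated blobs", {
  set.seed(29)
  emb <- rbind(matrix(rnorm(160), 80, 2), matrix(rnorm(160, 15), 80, 2))
  g <- knn_from_matrix(emb, 10)
  cl <- cluster_types(g, seed = 0)
  expect_length(cl, 160)
  blob <- rep(c(1, 2), each = 80)
  # each blob maps to a single set of clusters disjoint from the other blob
  expect_length(intersect(unique(cl[blob == 1]), unique(cl[blob == 2])), 0)
  expect_identical(cluster_types(g, seed = 0), cl)
})
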