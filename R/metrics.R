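#' k-BET neighborhood batch-mixing test
#'
#' For each tested observation `j`, compares the batch composition of its
#' `k` nearest neighbors with the global batch frequencies `f` via the
#' Pearson chi-square statistic
#' \deqn{\kappa_j^k = \sum_{i=1}^{l} (n_{ji}^k - f_i k)^2 / (f_i k)}
#' referred to a chi-square distribution with `l - 1` degrees of freedom
#' (`l` = number of batches present globally). A neighborhood is accepted
#' when its p-value exceeds `alpha`; a well-mixed integration accepts most
#' neighborhoods.
#'
#' @param graph a `NeighborGraph` (use `k >= 10` for chi-square adequacy).
#' @param batch batch labels for every observation in the graph.
#' @param alpha significance level (default 0.05).
#' @param sample_fraction fraction of neighborhoods tested (at least 100, or
#'   all of them when N is smaller).
#' @param seed seed for the neighborhood subsample.
#' @return a `KbetResult`: `chi_mean`, `p_summary` (mean p over tested
#'   neighborhoods), `accept_rate`, `reject_rate`, `k`, `l`, `f`, `tested`.
#' @export
kbet <- function(graph, batch, alpha = 0.05, sample_fraction = 0.1, seed = 0) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least two batches")
  if (graph$k < 10L) warning("k < 10: chi-square approximation may be poor")
  n <- nrow(graph$indices)
  k <- graph$k
  f <- as.numeric(table(batch)) / n
  keep <- f > 0
  l <- sum(keep)
  m <- min(n, max(100L, ceiling(sample_fraction * n)))
  set.seed(seed)
  tested <- sort(sample(n, m))
  y <- as.integer(batch)
  expected <- f[keep] * k
  kappa <- numeric(m)
  for (ii in seq_len(m)) {
    nb <- y[graph$indices[tested[ii], ]]
    cnt <- tabulate(nb, nbins = nlevels(batch))[keep]
    kappa[ii] <- sum((cnt - expected)^2 / expected)
  }
  p <- stats::pchisq(kappa, df = l - 1, lower.tail = FALSE)
  acc <- mean(p > alpha)
  structure(list(chi_mean = mean(kappa), p_summary = mean(p),
                 accept_rate = acc, reject_rate = 1 - acc,
                 k = k, l = l, f = f, alpha = alpha, tested = tested,
                 kappa = kappa, p_values = p),
            class = "KbetResult")
}

# Per-observation inverse Simpson index of `labels` over each neighborhood
# (the observation itself plus its k neighbors); raw values in [1, #levels].
inverse_simpson <- function(graph, labels) {
  labels <- factor(labels)
  y <- as.integer(labels)
  n <- nrow(graph$indices)
  raw <- numeric(n)
  for (j in seq_len(n)) {
    ids <- c(j, graph$indices[j, ])
    p <- tabulate(y[ids], nbins = nlevels(labels)) / length(ids)
    raw[j] <- 1 / sum(p^2)
  }
  raw
}

minmax_norm <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' LISI mixing and biology-preservation scores
#'
#' The local inverse Simpson index of a label set is `1 / sum(p^2)` with `p`
#' the label proportions in each observation's neighborhood (itself plus its
#' `k` nearest neighbors). Raw per-observation values lie in
#' `[1, #labels]`; each label set's vector is min-max normalized to `[0, 1]`
#' and averaged. Batch labels give `iLISI` (higher = better mixing); cell or
#' domain-type labels give `cLISI` (lower = better biology preservation).
#'
#' @param graph a `NeighborGraph`.
#' @param batch batch labels.
#' @param types cell/domain-type labels (may be fallback cluster labels, see
#'   [cluster_types()]).
#' @return a `LisiResult`: `iLISI`, `cLISI`, `raw_ilisi`, `raw_clisi`
#'   (per-observation raw values); `f1` is left for [f1_lisi()].
#' @export
lisi_scores <- function(graph, batch, types) {
  score_one <- function(labels, what) {
    labels <- factor(labels)
    if (nlevels(labels) < 2L) {
      warning(what, " has a single level; LISI defined as 0")
      return(list(norm = 0, raw = rep(1, nrow(graph$indices))))
    }
    raw <- inverse_simpson(graph, labels)
    list(norm = mean(minmax_norm(raw)), raw = raw)
  }
  b <- score_one(batch, "batch")
  c_ <- score_one(types, "types")
  structure(list(iLISI = b$norm, cLISI = c_$norm,
                 raw_ilisi = b$raw, raw_clisi = c_$raw),
            class = "LisiResult")
}

#' F1 combination of the LISI pair
#'
#' \deqn{F1 = \frac{2 (1 - cLISI)\, iLISI}{(1 - cLISI) + iLISI}}
#' the harmonic mean of batch mixing (`iLISI`) and biology preservation
#' (`1 - cLISI`); 0 when the denominator vanishes.
#'
#' @param iLISI,cLISI normalized scores in [0, 1].
#' @return F1 score in [0, 1].
#' @export
f1_lisi <- function(iLISI, cLISI) {
  stopifnot(iLISI >= 0, iLISI <= 1, cLISI >= 0, cLISI <= 1)
  denom <- (1 - cLISI) + iLISI
  if (denom == 0) return(0)
  2 * (1 - cLISI) * iLISI / denom
}

#' Mean silhouette coefficients under batch and type labels
#'
#' The standard silhouette coefficient (Euclidean, full pairwise distances)
#' averaged over observations, once with batch labels (`iSS`; high values
#' mean batches separate, i.e. poor mixing) and once with type labels
#' (`cSS`; high values mean biology separates, i.e. good preservation).
#' Above `max_n` observations a seeded subsample keeps the O(N^2) distance
#' matrix tractable.
#'
#' @param embedding N x d numeric matrix.
#' @param batch batch labels.
#' @param types type labels.
#' @param max_n subsample cap (default 10000).
#' @param seed subsample seed.
#' @return a `SilhouetteResult`: `iSS`, `cSS`, `iSS_prime`, `cSS_prime`
#'   (the `(1 + s)/2` rescalings); `f1` and `mode` are left for [f1_ss()].
#' @export
silhouette_scores <- function(embedding, batch, types, max_n = 10000, seed = 0) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 3L) stop("need at least three observations")
  idx <- seq_len(n)
  if (n > max_n) {
    set.seed(seed)
    idx <- sort(sample(n, max_n))
  }
  d <- stats::dist(embedding[idx, , drop = FALSE])
  mean_sil <- function(labels, what) {
    labels <- factor(labels[idx])
    if (nlevels(labels) < 2L) {
      warning(what, " has a single level; silhouette defined as 0")
      return(0)
    }
    sil <- cluster::silhouette(as.integer(labels), d)
    mean(sil[, "sil_width"])
  }
  iSS <- mean_sil(batch, "batch")
  cSS <- mean_sil(types, "types")
  structure(list(iSS = iSS, cSS = cSS,
                 iSS_prime = (1 + iSS) / 2, cSS_prime = (1 + cSS) / 2),
            class = "SilhouetteResult")
}

#' F1 combination of the silhouette pair
#'
#' Two conventions are exposed. `"table_consistent"` (default) combines the
#' raw means clipped to [0, 1]:
#' \deqn{F1 = \frac{2 (1 - iSS)\, cSS}{(1 - iSS) + cSS}}
#' `"equation_9"` first rescales both to `s' = (1 + s)/2` and applies the
#' same form to the primed values. The two disagree; the table-consistent
#' form is the one whose outputs match the published summary tables of this
#' metric family, so it is the default, with the primed form kept for
#' comparison (see the methods vignette).
#'
#' @param iSS,cSS mean silhouettes in [-1, 1].
#' @param mode `"table_consistent"` or `"equation_9"`.
#' @return F1 score in [0, 1].
#' @export
f1_ss <- function(iSS, cSS, mode = c("table_consistent", "equation_9")) {
  mode <- match.arg(mode)
  stopifnot(iSS >= -1, iSS <= 1, cSS >= -1, cSS <= 1)
  clip01 <- function(v) min(max(v, 0), 1)
  if (mode == "table_consistent") {
    i <- clip01(iSS); c_ <- clip01(cSS)
    denom <- (1 - i) + c_
    if (denom == 0) return(0)
    2 * (1 - i) * c_ / denom
  } else {
    ip <- (1 + iSS) / 2; cp <- (1 + cSS) / 2
    denom <- (1 - ip) + cp
    if (denom == 0) return(0)
    2 * (1 - ip) * cp / denom
  }
}

#' Composite batch-effect score
#'
#' The unweighted mean of the LISI F1, the silhouette F1 and the classifier
#' accept rate (`1 - DomainAcc`). All three lie in [0, 1]; higher means a
#' better-mixed, biology-preserving integration.
#'
#' @param f1_lisi,f1_ss,accept_rate component scores in [0, 1].
#' @return a `SummaryScore`: the three components and `batcheval`, their
#'   mean.
#' @export
batcheval_score <- function(f1_lisi, f1_ss, accept_rate) {
  stopifnot(f1_lisi >= 0, f1_lisi <= 1, f1_ss >= 0, f1_ss <= 1,
            accept_rate >= 0, accept_rate <= 1)
  structure(list(f1_lisi = f1_lisi, f1_ss = f1_ss, accept_rate = accept_rate,
                 batcheval = mean(c(f1_lisi, f1_ss, accept_rate))),
            class = "SummaryScore")
}

#' Fallback cluster labels from the kNN graph
#'
#' When no cell/domain-type annotation is available, Leiden community
#' detection on the (symmetrized, unweighted) kNN graph of the PCA embedding
#' provides cluster labels so the type-based metrics (`cLISI`, `cSS`) can
#' still be computed; reports mark such scores as cluster-based.
#'
#' @param graph a `NeighborGraph`.
#' @param resolution Leiden resolution (default 1.0).
#' @param seed clustering seed.
#' @return factor of cluster labels, length N.
#' @export
cluster_types <- function(graph, resolution = 1.0, seed = 0) {
  n <- nrow(graph$indices)
  edges <- cbind(rep(seq_len(n), each = graph$k), as.vector(t(graph$indices)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  factor(paste0("cluster_", igraph::membership(cl)))
}
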