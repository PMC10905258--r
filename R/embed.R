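#' PCA embedding of the normalized layer
#'
#' Projects the normalized expression matrix onto its leading principal
#' components and stores the scores under `embeddings$pca`. The sign of each
#' component is fixed so that the largest-magnitude loading is positive,
#' making the embedding reproducible across platforms.
#'
#' @param ds an [IntegratedDataset] with `layers$normalized` (see
#'   [normalize_dataset()]).
#' @param n_components number of components; must be below `min(N, genes)`.
#' @param seed unused by the deterministic exact solver; kept so every
#'   embedding step shares one signature.
#' @return `ds` with `embeddings$pca` set (N x n_components).
#' @export
pca_embed <- function(ds, n_components = 50, seed = 0) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing; run normalize_dataset() first")
  x <- ds$layers$normalized
  if (n_components >= min(nrow(x), ncol(x))) {
    stop("n_components (", n_components, ") must be < min(N, genes) = ", min(dim(x)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- ds$obs_ids
  ds$embeddings$pca <- scores
  attr(ds$embeddings$pca, "sdev") <- pc$sdev
  ds
}

#' UMAP embedding of the PCA scores
#'
#' Two-dimensional UMAP layout of the PCA embedding, for display panels.
#' Runs single-threaded so a fixed seed gives an identical layout.
#'
#' @param ds an [IntegratedDataset] with `embeddings$pca`.
#' @param n_neighbors UMAP neighborhood size; requires `N >= n_neighbors + 1`.
#' @param seed random seed.
#' @return `ds` with `embeddings$umap` set (N x 2).
#' @export
umap_embed <- function(ds, n_neighbors = 15, seed = 0) {
  if (is.null(ds$embeddings$pca)) stop("pca embedding missing; run pca_embed() first")
  n <- n_obs(ds)
  if (n < n_neighbors + 1) {
    stop("N = ", n, " observations is too few for n_neighbors = ", n_neighbors)
  }
  set.seed(seed)
  um <- uwot::umap(ds$embeddings$pca, n_neighbors = n_neighbors,
                   n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  rownames(um) <- ds$obs_ids
  colnames(um) <- c("UMAP1", "UMAP2")
  ds$embeddings$umap <- um
  ds
}

#' Exact k-nearest-neighbor graph in a named embedding
#'
#' Brute-force Euclidean k-NN with the observation itself excluded and
#' distance ties broken by the lower observation index, so the graph is a
#' pure function of the embedding.
#'
#' @param ds an [IntegratedDataset].
#' @param embedding_name name of an entry of `ds$embeddings`.
#' @param k neighborhood size, below N.
#' @return a `NeighborGraph`: list with `indices` (N x k integer matrix of
#'   neighbor row indices), `k`, `metric`, `embedding`.
#' @export
knn_neighbors <- function(ds, embedding_name = "pca", k = 25) {
  emb <- ds$embeddings[[embedding_name]]
  if (is.null(emb)) {
    stop("unknown embedding '", embedding_name, "'; available: ",
         paste(names(ds$embeddings), collapse = ", "))
  }
  g <- knn_from_matrix(emb, k)
  g$embedding <- embedding_name
  g
}

#' k-NN graph from a raw embedding matrix
#' @param emb N x d numeric matrix.
#' @param k neighborhood size, below N.
#' @return a `NeighborGraph` (see [knn_neighbors()]).
#' @export
knn_from_matrix <- function(emb, k) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (k >= n) stop("k (", k, ") must be < N (", n, ")")
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared Euclidean distances, numerically clipped at zero
    d2 <- pmax(outer(sq[rows], sq, `+`) - 2 * tcrossprod(emb[rows, , drop = FALSE], emb), 0)
    for (i in seq_along(rows)) {
      d <- d2[i, ]
      d[rows[i]] <- Inf  # no self-loop
      idx[rows[i], ] <- order(d)[seq_len(k)]  # stable order => ties to lower index
    }
  }
  structure(list(indices = idx, k = as.integer(k), metric = "euclidean",
                 embedding = NA_character_),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat("NeighborGraph:", nrow(x$indices), "observations, k =", x$k,
      "(", x$metric, "on", x$embedding, ")\n")
  invisible(x)
}
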