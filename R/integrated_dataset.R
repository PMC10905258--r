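#' Construct an IntegratedDataset
#'
#' The central container of the package: a merged observations x genes count
#' matrix with a batch label per observation, optional cell/domain-type
#' labels, optional 2-D spatial coordinates, and named low-dimensional
#' embeddings and transformed layers. Observations (spots or cells) are rows
#' everywhere.
#'
#' @param matrix numeric matrix or Matrix, observations x genes, non-negative
#'   and finite.
#' @param batch character or factor of length `nrow(matrix)`; the batch
#'   (tissue section / dataset) each observation came from.
#' @param obs_ids observation identifiers; defaults to rownames or `obs_1..N`.
#' @param gene_ids gene identifiers; defaults to colnames or `gene_1..G`.
#' @param cell_type optional character or factor of cell/domain-type labels.
#' @param spatial optional N x 2 numeric matrix of spatial coordinates.
#' @param embeddings named list of N-row numeric matrices (e.g. `"pca"`).
#' @param layers named list of transformed matrices with the same dimensions
#'   as `matrix` (e.g. `"normalized"`).
#' @return an object of class `IntegratedDataset`.
#' @export
IntegratedDataset <- function(matrix, batch, obs_ids = NULL, gene_ids = NULL,
                              cell_type = NULL, spatial = NULL,
                              embeddings = list(), layers = list()) {
  if (!is.matrix(matrix) && !methods::is(matrix, "Matrix")) {
    matrix <- as.matrix(matrix)
  }
  n <- nrow(matrix)
  if (is.null(obs_ids)) {
    obs_ids <- if (!is.null(rownames(matrix))) rownames(matrix) else paste0("obs_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(colnames(matrix))) colnames(matrix) else paste0("gene_", seq_len(ncol(matrix)))
  }
  ds <- structure(
    list(
      matrix = matrix,
      obs_ids = as.character(obs_ids),
      gene_ids = as.character(gene_ids),
      batch = factor(batch),
      cell_type = if (is.null(cell_type)) NULL else factor(cell_type),
      spatial = spatial,
      embeddings = embeddings,
      layers = layers
    ),
    class = "IntegratedDataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate an IntegratedDataset
#'
#' Checks the container invariants: consistent dimensions, at least one
#' observation per batch, non-negative finite counts, and N rows in every
#' embedding/layer. Called by the constructor; exported so pipelines can
#' re-check after manual edits.
#'
#' @param ds an `IntegratedDataset`.
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "IntegratedDataset"))
  n <- nrow(ds$matrix)
  if (length(ds$batch) != n) {
    stop("batch labels (", length(ds$batch), ") do not match observations (", n, ")")
  }
  if (length(ds$obs_ids) != n) {
    stop("obs_ids length does not match observation count")
  }
  if (length(ds$gene_ids) != ncol(ds$matrix)) {
    stop("gene_ids length does not match gene count")
  }
  if (anyNA(ds$batch)) stop("batch labels contain NA")
  if (any(table(ds$batch) < 1L) || nlevels(ds$batch) < 1L) {
    stop("every batch must contain at least one observation")
  }
  vals <- if (methods::is(ds$matrix, "sparseMatrix")) ds$matrix@x else ds$matrix
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
    stop("count matrix must be non-negative and finite")
  }
  if (!is.null(ds$cell_type) && length(ds$cell_type) != n) {
    stop("cell_type length does not match observation count")
  }
  if (!is.null(ds$spatial) && (nrow(ds$spatial) != n || ncol(ds$spatial) != 2L)) {
    stop("spatial coordinates must be an N x 2 matrix")
  }
  for (nm in names(ds$embeddings)) {
    if (nrow(ds$embeddings[[nm]]) != n) {
      stop("embedding '", nm, "' does not have N rows")
    }
  }
  for (nm in names(ds$layers)) {
    if (!all(dim(ds$layers[[nm]]) == dim(ds$matrix))) {
      stop("layer '", nm, "' does not match matrix dimensions")
    }
  }
  invisible(ds)
}

#' @export
print.IntegratedDataset <- function(x, ...) {
  cat("IntegratedDataset:", nrow(x$matrix), "observations x", ncol(x$matrix), "genes\n")
  cat("  batches:", paste0(levels(x$batch), " (", as.integer(table(x$batch)), ")", collapse = ", "), "\n")
  if (!is.null(x$cell_type)) cat("  cell types:", nlevels(x$cell_type), "\n")
  if (!is.null(x$spatial)) cat("  spatial: yes\n")
  if (length(x$embeddings)) cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  if (length(x$layers)) cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Number of observations
#' @param ds an `IntegratedDataset`.
#' @return integer N.
#' @export
n_obs <- function(ds) nrow(ds$matrix)

#' Per-batch observation counts
#' @param ds an `IntegratedDataset`.
#' @return named integer vector of batch sizes n_i.
#' @export
batch_sizes <- function(ds) {
  tab <- table(ds$batch)
  stats::setNames(as.integer(tab), names(tab))
}
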