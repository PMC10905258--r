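#' Min-max log normalization
#'
#' Rescales the whole expression matrix by its global minimum and maximum and
#' applies `log1p`:
#' \deqn{\hat x = \log(1 + (x - x_{min}) / (x_{max} - x_{min}))}
#' The extrema are taken over the entire merged matrix, not per gene, which
#' keeps values comparable across batches; output lies in `[0, log 2]`.
#'
#' @param x non-negative finite numeric matrix (observations x genes).
#' @return normalized matrix of the same shape. A constant matrix (max equal
#'   to min) returns all zeros with a warning.
#' @export
minmax_log_normalize <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < 0)) stop("matrix must be non-negative and finite")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant matrix: min-max range is zero, returning all zeros")
    return(array(0, dim = dim(x), dimnames = dimnames(x)))
  }
  log1p((x - rng[1]) / (rng[2] - rng[1]))
}

#' Attach the normalized layer to a dataset
#' @param ds an [IntegratedDataset] with raw counts in `$matrix`.
#' @return `ds` with `layers$normalized` filled.
#' @export
normalize_dataset <- function(ds) {
  ds$layers$normalized <- minmax_log_normalize(ds$matrix)
  ds
}

#' Total expression counts per observation
#'
#' Row sums of the raw count matrix: the library size of each spot/cell,
#' the quantity the distribution tests and density panels operate on.
#'
#' @param ds an [IntegratedDataset].
#' @return numeric vector of N totals.
#' @export
per_cell_total_counts <- function(ds) {
  as.numeric(Matrix::rowSums(ds$matrix))
}

#' Gene-wise mean and variance, optionally per batch
#'
#' Descriptive summaries behind the mean-variance scatter panel. Variance is
#' the population variance (denominator N), matching its descriptive role.
#'
#' @param ds an [IntegratedDataset].
#' @param by_batch compute one row per (batch, gene) instead of per gene.
#' @return data.frame with columns `batch` (or `"all"`), `gene`, `mean`,
#'   `variance`.
#' @export
per_gene_mean_variance <- function(ds, by_batch = FALSE) {
  mv <- function(m, label) {
    m <- as.matrix(m)
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    data.frame(batch = label, gene = ds$gene_ids, mean = mu,
               variance = pmax(v, 0), row.names = NULL)
  }
  if (!by_batch) return(mv(ds$matrix, "all"))
  out <- lapply(levels(ds$batch), function(b) {
    mv(ds$matrix[ds$batch == b, , drop = FALSE], b)
  })
  do.call(rbind, out)
}
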