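#' Load an expression dataset from disk
#'
#' Reads one batch (or a pre-merged multi-batch table) into an
#' [IntegratedDataset]. Three dialects are supported:
#' \describe{
#'   \item{csv}{dense CSV/TSV, observations in rows, a header row of gene
#'     names, the first column holding observation identifiers; metadata
#'     columns (batch, cell type) live alongside the gene columns and are
#'     pulled out by name.}
#'   \item{mtx}{a MatrixMarket directory or `matrix.mtx` path with
#'     `barcodes.tsv` and `features.tsv` sidecars (genes x cells on disk, as
#'     written by common quantifiers; transposed on load).}
#'   \item{h5ad}{AnnData; converted through the installed Python `anndata`
#'     into an MTX trio plus obs table in a temporary directory, then loaded
#'     by the MTX path. Requires a `python` with `anndata` on the PATH.}
#' }
#'
#' @param path file (csv, h5ad) or directory/`matrix.mtx` path (mtx).
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @param batch_key name of the metadata column holding batch labels (csv,
#'   h5ad). Absent columns raise an error listing what is available.
#' @param batch constant batch label applied to every observation when no
#'   metadata column exists (the usual case for a single-section MTX).
#' @param celltype_key optional metadata column with cell/domain-type labels.
#' @param sep field separator for `format = "csv"`.
#' @return a validated [IntegratedDataset].
#' @export
load_dataset <- function(path, format = c("csv", "mtx", "h5ad"),
                         batch_key = NULL, batch = NULL,
                         celltype_key = NULL, sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(batch_key) && is.null(batch)) {
    stop("supply either `batch_key` (metadata column) or `batch` (constant label)")
  }
  switch(format,
    csv = load_csv(path, batch_key, batch, celltype_key, sep),
    mtx = load_mtx(path, batch_key, batch, celltype_key),
    h5ad = load_h5ad(path, batch_key, batch, celltype_key)
  )
}

load_csv <- function(path, batch_key, batch, celltype_key, sep) {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  obs_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  meta_cols <- c(batch_key, celltype_key)
  missing <- setdiff(meta_cols, colnames(df))
  if (length(missing)) {
    stop("column(s) ", paste(sQuote(missing), collapse = ", "),
         " not found; available columns: ", paste(colnames(df), collapse = ", "))
  }
  batch_lab <- if (!is.null(batch_key)) df[[batch_key]] else rep(batch, nrow(df))
  ct <- if (!is.null(celltype_key)) df[[celltype_key]] else NULL
  gene_cols <- setdiff(colnames(df), meta_cols)
  mat <- as.matrix(df[, gene_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- obs_ids
  IntegratedDataset(mat, batch = batch_lab, obs_ids = obs_ids,
                    gene_ids = gene_cols, cell_type = ct)
}

mtx_sidecar <- function(dir, stems) {
  for (s in stems) {
    p <- file.path(dir, s)
    if (file.exists(p)) return(p)
  }
  stop("no ", stems[1], " sidecar found in ", dir)
}

load_mtx <- function(path, batch_key, batch, celltype_key) {
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx_path <- if (dir.exists(path)) mtx_sidecar(dir, c("matrix.mtx", "matrix.mtx.gz")) else path
  m <- Matrix::readMM(mtx_path)
  barcodes <- utils::read.delim(mtx_sidecar(dir, c("barcodes.tsv", "barcodes.tsv.gz")),
                                header = FALSE, stringsAsFactors = FALSE)
  features <- utils::read.delim(mtx_sidecar(dir, c("features.tsv", "features.tsv.gz", "genes.tsv")),
                                header = FALSE, stringsAsFactors = FALSE)
  mat <- Matrix::t(m)  # on disk: genes x cells
  obs_ids <- barcodes[[1L]]
  gene_ids <- features[[1L]]
  obs_path <- file.path(dir, "obs.tsv")
  obs_meta <- if (file.exists(obs_path)) {
    utils::read.delim(obs_path, stringsAsFactors = FALSE)
  } else NULL
  pick <- function(key) {
    if (is.null(key)) return(NULL)
    if (is.null(obs_meta) || !key %in% colnames(obs_meta)) {
      stop("column ", sQuote(key), " not found; available columns: ",
           if (is.null(obs_meta)) "(no obs.tsv sidecar)" else paste(colnames(obs_meta), collapse = ", "))
    }
    obs_meta[[key]]
  }
  batch_lab <- if (!is.null(batch_key)) pick(batch_key) else rep(batch, nrow(mat))
  IntegratedDataset(mat, batch = batch_lab, obs_ids = obs_ids,
                    gene_ids = gene_ids, cell_type = pick(celltype_key))
}

load_h5ad <- function(path, batch_key, batch, celltype_key) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") stop("reading h5ad requires a `python` with anndata on the PATH")
  out <- tempfile("h5ad_export_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  code <- paste(
    "import sys, anndata, scipy.io, scipy.sparse, pandas as pd",
    "ad = anndata.read_h5ad(sys.argv[1])",
    "X = scipy.sparse.csr_matrix(ad.X)",
    "scipy.io.mmwrite(sys.argv[2] + '/matrix.mtx', X.T)",
    "pd.Series(ad.obs_names).to_csv(sys.argv[2] + '/barcodes.tsv', sep='\\t', index=False, header=False)",
    "pd.Series(ad.var_names).to_csv(sys.argv[2] + '/features.tsv', sep='\\t', index=False, header=False)",
    "ad.obs.to_csv(sys.argv[2] + '/obs.tsv', sep='\\t', index=False)",
    sep = "; ")
  res <- system2(python, c("-c", shQuote(code), shQuote(path), shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("h5ad conversion failed: ", paste(res, collapse = "\n"))
  }
  load_mtx(out, batch_key, batch, celltype_key)
}

#' Merge multiple datasets into one multi-batch dataset
#'
#' Concatenates observations; the gene universe follows `gene_policy`:
#' `"intersection"` keeps genes present in every input (so downstream
#' distribution tests compare totals over the same genes across platforms),
#' `"union_zero_fill"` keeps every gene and fills absences with zero counts.
#' Each input contributes one (or more, if already multi-batch) batch level;
#' observation identifiers are deduplicated by suffixing the batch name.
#'
#' @param datasets list of at least two [IntegratedDataset] objects.
#' @param gene_policy `"intersection"` (default) or `"union_zero_fill"`.
#' @param batch_names optional character vector naming each input's batch;
#'   defaults to the inputs' existing batch labels, or `batch0..` when an
#'   input has a single unnamed level colliding with another input.
#' @return the merged [IntegratedDataset].
#' @export
merge_datasets <- function(datasets, gene_policy = c("intersection", "union_zero_fill"),
                           batch_names = NULL) {
  gene_policy <- match.arg(gene_policy)
  if (length(datasets) < 2L) stop("need at least two datasets to merge")
  if (!is.null(batch_names)) {
    if (length(batch_names) != length(datasets)) {
      stop("batch_names must match the number of datasets")
    }
    if (anyDuplicated(batch_names)) stop("duplicate batch names: ",
                                         paste(batch_names[duplicated(batch_names)], collapse = ", "))
  }
  gene_sets <- lapply(datasets, function(d) d$gene_ids)
  genes <- if (gene_policy == "intersection") {
    Reduce(intersect, gene_sets)
  } else {
    unique(unlist(gene_sets))
  }
  if (length(genes) == 0L) stop("empty gene intersection across datasets")

  pieces <- vector("list", length(datasets))
  batches <- vector("list", length(datasets))
  types <- vector("list", length(datasets))
  ids <- vector("list", length(datasets))
  have_types <- all(vapply(datasets, function(d) !is.null(d$cell_type), logical(1)))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    bn <- if (!is.null(batch_names)) batch_names[i] else NULL
    m <- as.matrix(d$matrix)
    colnames(m) <- d$gene_ids
    block <- matrix(0, nrow(m), length(genes), dimnames = list(NULL, genes))
    common <- intersect(genes, d$gene_ids)
    block[, common] <- m[, common, drop = FALSE]
    pieces[[i]] <- block
    lab <- if (!is.null(bn)) rep(bn, nrow(m)) else as.character(d$batch)
    batches[[i]] <- lab
    types[[i]] <- if (have_types) as.character(d$cell_type) else NULL
    ids[[i]] <- paste(d$obs_ids, lab, sep = "-")
  }
  batch_all <- unlist(batches)
  if (is.null(batch_names)) {
    # labels must distinguish inputs; collide -> error
    per_input <- lapply(batches, unique)
    if (any(table(unlist(per_input)) > 1L)) {
      stop("duplicate batch names across inputs; pass `batch_names` to disambiguate")
    }
  }
  IntegratedDataset(
    do.call(rbind, pieces),
    batch = batch_all,
    obs_ids = make.unique(unlist(ids)),
    gene_ids = genes,
    cell_type = if (have_types) unlist(types) else NULL,
    spatial = if (all(vapply(datasets, function(d) !is.null(d$spatial), logical(1)))) {
      do.call(rbind, lapply(datasets, function(d) d$spatial))
    } else NULL
  )
}

#' Export a benchmark summary as JSON
#'
#' Writes every number shown in the HTML report, at full precision, to a
#' machine-readable JSON document that [import_metrics()] round-trips.
#'
#' @param summary a `BenchmarkSummary` from [run_benchmark()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_metrics <- function(summary, path) {
  payload <- summary_to_list(summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Re-read exported metrics
#' @param path a JSON file written by [export_metrics()].
#' @return the metrics payload as a nested list.
#' @export
import_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

summary_to_list <- function(summary) {
  stopifnot(inherits(summary, "BenchmarkSummary"))
  variants <- lapply(summary$variants, function(v) {
    list(
      classifier = v$classifier[c("n_batch", "n_sample", "train_size", "domain_acc", "accept_rate")],
      kbet = v$kbet[c("chi_mean", "p_summary", "accept_rate", "reject_rate", "k", "l")],
      lisi = v$lisi[c("iLISI", "cLISI", "f1")],
      silhouette = v$silhouette[c("iSS", "cSS", "iSS_prime", "cSS_prime", "f1", "mode")],
      batcheval = v$score$batcheval
    )
  })
  list(variants = variants, recommended = summary$recommended,
       conclusion = summary$conclusion)
}
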