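.method_registry <- new.env(parent = emptyenv())

#' Register a batch-correction method
#'
#' A method is a function taking an [IntegratedDataset] and returning either
#' a corrected embedding (N x d matrix) or a corrected expression matrix
#' (N x genes, re-embedded by PCA before evaluation). Registered methods can
#' be named in [run_benchmark()].
#'
#' @param name unique method name.
#' @param transform the correction function.
#' @param provenance `"builtin"` or `"plugin"`.
#' @param overwrite allow replacing an existing entry.
#' @return the name, invisibly.
#' @export
register_method <- function(name, transform, provenance = "plugin", overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(transform))
  if (!overwrite && exists(name, envir = .method_registry, inherits = FALSE)) {
    stop("method '", name, "' is already registered")
  }
  assign(name, list(name = name, transform = transform, provenance = provenance),
         envir = .method_registry)
  invisible(name)
}

#' List registered correction methods
#' @return character vector of method names.
#' @export
list_methods <- function() sort(ls(.method_registry))

get_method <- function(name) {
  if (!exists(name, envir = .method_registry, inherits = FALSE)) {
    stop("unknown method '", name, "'; registered: ",
         paste(list_methods(), collapse = ", "))
  }
  get(name, envir = .method_registry, inherits = FALSE)
}

#' Register adapters for optional external correction tools
#'
#' Looks for the named packages and registers a thin adapter for each one
#' found; missing packages are skipped with a notice so the benchmark run
#' degrades gracefully rather than failing.
#'
#' @param packages packages to probe (default `"harmony"`).
#' @return character vector of adapter names actually registered.
#' @export
register_optional_adapters <- function(packages = c("harmony")) {
  registered <- character(0)
  for (pkg in packages) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      message("optional correction package '", pkg, "' not installed; adapter skipped")
      next
    }
    if (pkg == "harmony") {
      register_method("harmony", function(ds) {
        if (is.null(ds$embeddings$pca)) stop("harmony adapter needs a pca embedding")
        harmony::RunHarmony(ds$embeddings$pca, meta_data = data.frame(batch = ds$batch),
                            vars_use = "batch", verbose = FALSE)
      }, provenance = "plugin", overwrite = TRUE)
      registered <- c(registered, "harmony")
    }
  }
  registered
}

#' Built-in baseline correction: per-batch centering and scaling
#'
#' Standardizes the PCA scores within each batch (subtract the batch mean,
#' divide by the batch standard deviation; sd of a size-1 or constant batch
#' is treated as 1). Removes location/scale batch shifts in embedding space;
#' a dependency-free reference point for the benchmark loop.
#'
#' @param ds an [IntegratedDataset] with `embeddings$pca`.
#' @return corrected N x d embedding matrix.
#' @export
baseline_center_scale <- function(ds) {
  if (is.null(ds$embeddings$pca)) stop("pca embedding missing; run pca_embed() first")
  emb <- ds$embeddings$pca
  out <- emb
  for (b in levels(ds$batch)) {
    rows <- ds$batch == b
    block <- emb[rows, , drop = FALSE]
    mu <- colMeans(block)
    sdv <- apply(block, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    out[rows, ] <- sweep(sweep(block, 2, mu), 2, sdv, `/`)
  }
  out
}

# Full metric bundle for one variant: classifier + k-BET + LISI + silhouette
# + composite score, all in the variant's evaluation embedding.
evaluate_variant <- function(embedding, batch, types, config,
                             classifier_features = NULL) {
  n <- nrow(embedding)
  kbet_k <- min(config$kbet_k, n - 1L)
  lisi_k <- min(config$lisi_k, n - 1L)
  g_kbet <- knn_from_matrix(embedding, kbet_k)
  g_lisi <- if (lisi_k == kbet_k) g_kbet else knn_from_matrix(embedding, lisi_k)

  feats <- if (is.null(classifier_features)) embedding else classifier_features
  clf <- classifier_fit(feats, batch, config$classifier)
  kb <- kbet(g_kbet, batch, alpha = config$alpha,
             sample_fraction = config$kbet_sample_fraction,
             seed = derive_seed(config$seed, 3L))
  li <- lisi_scores(g_lisi, batch, types)
  li$f1 <- f1_lisi(li$iLISI, li$cLISI)
  si <- silhouette_scores(embedding, batch, types,
                          max_n = config$silhouette_max_n,
                          seed = derive_seed(config$seed, 4L))
  si$mode <- config$f1_ss_mode
  si$f1 <- f1_ss(si$iSS, si$cSS, mode = config$f1_ss_mode)
  sc <- batcheval_score(li$f1, si$f1, clf$accept_rate)
  list(classifier = clf, kbet = kb, lisi = li, silhouette = si, score = sc,
       embedding = embedding)
}

#' Benchmark batch-correction methods against the raw integration
#'
#' Computes the full metric bundle (domain classifier, k-BET, LISI,
#' silhouette, composite score) for the raw PCA embedding and for each
#' correction method's output space, under identical seeds. Type-based
#' metrics use the dataset's cell-type labels, or Leiden cluster labels as
#' fallback (marked in the result). A method that raises is recorded as
#' failed; the other variants are unaffected.
#'
#' @param ds an [IntegratedDataset] (>= 2 batches). Normalization and PCA
#'   are computed on the fly when missing.
#' @param methods character vector of registered method names, or a named
#'   list of correction functions.
#' @param config a [batcheval_config()].
#' @return a `BenchmarkSummary`: `variants` (named metric bundles, `"Raw"`
#'   first), `failed`, `table` (k-BET accept / mean p / composite score
#'   grid), `recommended`, `conclusion`, `types_source`.
#' @export
run_benchmark <- function(ds, methods = "baseline", config = batcheval_config()) {
  if (nlevels(ds$batch) < 2L) stop("need at least two batches to evaluate")
  if (is.null(ds$layers$normalized)) ds <- normalize_dataset(ds)
  if (is.null(ds$embeddings$pca)) {
    ds <- pca_embed(ds, n_components = min(config$pca_components,
                                           min(dim(ds$matrix)) - 1L),
                    seed = derive_seed(config$seed, 0L))
  }
  types_source <- "cell_type"
  types <- ds$cell_type
  if (is.null(types)) {
    g <- knn_from_matrix(ds$embeddings$pca, min(config$kbet_k, n_obs(ds) - 1L))
    types <- cluster_types(g, resolution = config$leiden_resolution,
                           seed = derive_seed(config$seed, 5L))
    types_source <- "leiden clusters (fallback)"
  }

  if (is.character(methods)) {
    methods <- stats::setNames(lapply(methods, function(nm) get_method(nm)$transform),
                               methods)
  }
  variants <- list(
    Raw = evaluate_variant(ds$embeddings$pca, ds$batch, types, config,
                           classifier_features = switch(config$classifier_features,
                                                        normalized = ds$layers$normalized,
                                                        pca = ds$embeddings$pca))
  )
  failed <- list()
  for (nm in names(methods)) {
    res <- tryCatch({
      out <- methods[[nm]](ds)
      out <- as.matrix(out)
      if (nrow(out) != n_obs(ds)) stop("method output row count != N")
      if (any(!is.finite(out))) stop("method output contains non-finite values")
      if (ncol(out) == ncol(ds$matrix)) {
        # corrected expression layer -> evaluate in its PCA space
        tmp <- ds
        tmp$layers$normalized <- out
        tmp <- pca_embed(tmp, n_components = min(config$pca_components,
                                                 min(dim(out)) - 1L),
                         seed = derive_seed(config$seed, 0L))
        out <- tmp$embeddings$pca
      }
      evaluate_variant(out, ds$batch, types, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[nm]] <- conditionMessage(res)
      warning("method '", nm, "' failed: ", conditionMessage(res))
    } else {
      variants[[nm]] <- res
    }
  }

  tab <- data.frame(row.names = c("k-BET score", "95% p value", "BatchEval score"))
  for (nm in names(variants)) {
    v <- variants[[nm]]
    tab[[nm]] <- c(v$kbet$accept_rate, v$kbet$p_summary, v$score$batcheval)
  }
  summary <- structure(list(variants = variants, failed = failed, table = tab,
                            types_source = types_source,
                            recommended = NULL, conclusion = NULL),
                       class = "BenchmarkSummary")
  rec <- recommend(summary, threshold = config$batch_effect_threshold)
  summary$recommended <- rec$recommended
  summary$conclusion <- rec$conclusion
  summary
}

#' Recommendation from a benchmark summary
#'
#' When the raw composite score falls below `threshold` the dataset is
#' declared to have a batch effect and the corrected variant with the
#' highest composite score (ties broken alphabetically) is recommended;
#' otherwise no further processing is advised.
#'
#' @param summary a `BenchmarkSummary`.
#' @param threshold raw-score cutoff (default 0.5).
#' @return list with `recommended` (method name or `NA`) and `conclusion`.
#' @export
recommend <- function(summary, threshold = 0.5) {
  stopifnot(inherits(summary, "BenchmarkSummary"))
  raw <- summary$variants$Raw$score$batcheval
  corrected <- setdiff(names(summary$variants), "Raw")
  if (raw >= threshold) {
    return(list(recommended = NA_character_,
                conclusion = "This dataset shows no substantial batch effect; no further processing is required."))
  }
  if (length(corrected) == 0L) {
    return(list(recommended = NA_character_,
                conclusion = "This dataset has batch effect and requires further processing."))
  }
  scores <- vapply(corrected, function(nm) summary$variants[[nm]]$score$batcheval, numeric(1))
  best <- corrected[order(-scores, corrected)][1L]
  list(recommended = best,
       conclusion = paste0("This dataset has batch effect and requires further processing. ",
                           "Recommend to use \"", best, "\"."))
}

#' @export
print.BenchmarkSummary <- function(x, ...) {
  cat("BenchmarkSummary (", length(x$variants), "variants )\n")
  print(round(x$table, 4))
  cat(x$conclusion, "\n")
  invisible(x)
}
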