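#' Derive a per-module seed from the global seed
#'
#' One global seed fans out to per-module seeds as `(seed + offset) mod
#' (2^31 - 1)`, so every stochastic step is reproducible from a single
#' integer. Offsets: 0 PCA, 1 UMAP, 2 classifier, 3 k-BET sampling,
#' 4 silhouette subsampling, 5 clustering, 6 simulation.
#'
#' @param seed global integer seed.
#' @param offset module offset.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' Collects every tunable of the evaluation pipeline with its default:
#' significance level 0.05; 50 PCA components; 15 UMAP neighbors (display
#' only — metrics run in PCA space); k-BET neighborhoods of 25 with a 10\%
#' subsample (at least 100); LISI neighborhoods of 90; silhouette subsample
#' cap 10000; the classifier defaults of [classifier_config()] with
#' normalized gene features; silhouette F1 in table-consistent mode;
#' raw-score batch-effect threshold 0.5; global seed 0.
#'
#' @param alpha significance level for tests and k-BET.
#' @param pca_components PCA dimensionality.
#' @param umap_neighbors UMAP neighborhood size.
#' @param kbet_k k-BET neighborhood size.
#' @param kbet_sample_fraction fraction of neighborhoods k-BET tests.
#' @param lisi_k LISI neighborhood size.
#' @param silhouette_max_n silhouette subsample cap.
#' @param classifier a [classifier_config()].
#' @param classifier_features `"normalized"` or `"pca"` (raw variant only;
#'   corrected variants are always classified in their own embedding).
#' @param f1_ss_mode `"table_consistent"` or `"equation_9"`.
#' @param batch_effect_threshold raw composite score below which correction
#'   is recommended.
#' @param leiden_resolution fallback-clustering resolution.
#' @param seed global seed, fanned out via [derive_seed()].
#' @return a `BatchevalConfig` list.
#' @export
batcheval_config <- function(alpha = 0.05, pca_components = 50,
                             umap_neighbors = 15, kbet_k = 25,
                             kbet_sample_fraction = 0.1, lisi_k = 90,
                             silhouette_max_n = 10000,
                             classifier = classifier_config(),
                             classifier_features = c("normalized", "pca"),
                             f1_ss_mode = c("table_consistent", "equation_9"),
                             batch_effect_threshold = 0.5,
                             leiden_resolution = 1.0, seed = 0) {
  classifier_features <- match.arg(classifier_features)
  f1_ss_mode <- match.arg(f1_ss_mode)
  cfg <- structure(list(alpha = alpha, pca_components = as.integer(pca_components),
                        umap_neighbors = as.integer(umap_neighbors),
                        kbet_k = as.integer(kbet_k),
                        kbet_sample_fraction = kbet_sample_fraction,
                        lisi_k = as.integer(lisi_k),
                        silhouette_max_n = as.integer(silhouette_max_n),
                        classifier = classifier,
                        classifier_features = classifier_features,
                        f1_ss_mode = f1_ss_mode,
                        batch_effect_threshold = batch_effect_threshold,
                        leiden_resolution = leiden_resolution,
                        seed = as.integer(seed)),
                   class = "BatchevalConfig")
  cfg$classifier$seed <- derive_seed(cfg$seed, 2L)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror [batcheval_config()] (with a nested
#' `classifier` block for [classifier_config()]); unknown keys are rejected
#' so typos fail loudly.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `BatchevalConfig`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, overrides)
  clf_args <- vals$classifier
  vals$classifier <- NULL
  known <- names(formals(batcheval_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(clf_args)) {
    unknown <- setdiff(names(clf_args), names(formals(classifier_config)))
    if (length(unknown)) stop("unknown classifier config key(s): ", paste(unknown, collapse = ", "))
    vals$classifier <- do.call(classifier_config, clf_args)
  }
  do.call(batcheval_config, vals)
}

#' Run the end-to-end evaluation pipeline
#'
#' load/merge -> normalize -> PCA/UMAP -> statistical battery -> benchmark
#' (classifier + metrics + composite score for raw and each method) ->
#' figures -> HTML report, plus a JSON metrics sidecar and a run manifest.
#'
#' @param datasets a single [IntegratedDataset] or a list of them (merged
#'   with [merge_datasets()]).
#' @param methods correction methods for [run_benchmark()].
#' @param outdir report output directory (created if needed).
#' @param config a [batcheval_config()].
#' @param condition optional condition labels for the contingency analysis.
#' @return the `BenchmarkSummary`, invisibly; report under `outdir`.
#' @export
run_pipeline <- function(datasets, methods = "baseline", outdir,
                         config = batcheval_config(), condition = NULL) {
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline step '", what, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  t0 <- Sys.time()
  ds <- step("merge", {
    if (inherits(datasets, "IntegratedDataset")) datasets
    else if (length(datasets) == 1L) datasets[[1L]]
    else merge_datasets(datasets)
  })
  ds <- step("normalize", normalize_dataset(ds))
  ds <- step("pca", pca_embed(ds, n_components = min(config$pca_components,
                                                     min(dim(ds$matrix)) - 1L),
                              seed = derive_seed(config$seed, 0L)))
  ds <- step("umap", umap_embed(ds, n_neighbors = min(config$umap_neighbors,
                                                      n_obs(ds) - 1L),
                                seed = derive_seed(config$seed, 1L)))
  stats_bundle <- step("stat_tests", stat_test_battery(ds, condition, config$alpha))
  summary <- step("benchmark", run_benchmark(ds, methods, config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  step("report", render_report(summary, stats_bundle, ds, outdir, config))
  export_metrics(summary, file.path(outdir, "metrics.json"))
  manifest <- list(
    seed = config$seed,
    n_obs = n_obs(ds), n_genes = ncol(ds$matrix),
    batches = as.list(batch_sizes(ds)),
    methods = setdiff(names(summary$variants), "Raw"),
    failed = summary$failed,
    types_source = summary$types_source,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("batcheval")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
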