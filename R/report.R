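utils::globalVariables(c("total", "batch", "x", "y", "mean_expr", "variance",
                         "qx", "qy", "PC1", "PC2"))

slugify <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

placeholder_panel <- function(path, msg) {
  grDevices::png(path, width = 600, height = 450)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::text(0.5, 0.5, msg, cex = 1.2)
  grDevices::dev.off()
  path
}

save_panel <- function(p, path) {
  ggplot2::ggsave(path, p, width = 6, height = 4.5, dpi = 100)
  path
}

#' Render the visualization panels for one variant
#'
#' Produces the per-variant figure set: (a) kernel density of
#' per-observation totals by batch, (b) their empirical CDFs, (c) boxplots,
#' (d) gene mean-variance scatter by batch, (e) joint scatter of the first
#' two embedding dimensions with marginal densities, (f) UMAP colored by
#' batch, (g) pairwise Q-Q plots of totals for every batch pair. A panel
#' whose prerequisite is missing is replaced by a placeholder image and the
#' run continues.
#'
#' @param ds an [IntegratedDataset] (for totals / gene summaries / raw
#'   embeddings).
#' @param variant variant name used in file names and titles.
#' @param outdir output directory for PNG files.
#' @param embedding optional N x d matrix evaluated for this variant;
#'   defaults to the dataset's PCA scores.
#' @param seed seed for point subsampling and on-the-fly UMAP.
#' @param max_points scatter subsample cap.
#' @return list with `files` (named vector of 7 paths) and `qq_pairs`.
#' @export
render_figure_panels <- function(ds, variant = "Raw", outdir,
                                 embedding = NULL, seed = 0,
                                 max_points = 50000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tag <- slugify(variant)
  path_of <- function(p) file.path(outdir, paste0(tag, "_", p, ".png"))
  totals <- per_cell_total_counts(ds)
  df <- data.frame(total = totals, batch = ds$batch)
  multi <- nlevels(ds$batch) > 1L
  files <- character(0)

  files["density"] <- save_panel(
    ggplot2::ggplot(df, ggplot2::aes(total, colour = batch)) +
      ggplot2::geom_density() +
      ggplot2::labs(title = paste(variant, "- total counts, kernel density"),
                    x = "total counts per observation") +
      ggplot2::theme_minimal(),
    path_of("density"))
  files["cdf"] <- save_panel(
    ggplot2::ggplot(df, ggplot2::aes(total, colour = batch)) +
      ggplot2::stat_ecdf() +
      ggplot2::labs(title = paste(variant, "- total counts, empirical CDF"),
                    x = "total counts per observation", y = "F(x)") +
      ggplot2::theme_minimal(),
    path_of("cdf"))
  files["boxplot"] <- save_panel(
    ggplot2::ggplot(df, ggplot2::aes(batch, total, fill = batch)) +
      ggplot2::geom_boxplot(show.legend = FALSE) +
      ggplot2::labs(title = paste(variant, "- total counts by batch")) +
      ggplot2::theme_minimal(),
    path_of("boxplot"))

  mv <- per_gene_mean_variance(ds, by_batch = multi)
  names(mv)[names(mv) == "mean"] <- "mean_expr"
  mv <- mv[mv$mean_expr > 0 & mv$variance > 0, , drop = FALSE]  # log-log axes
  files["mean_variance"] <- save_panel(
    ggplot2::ggplot(mv, ggplot2::aes(mean_expr, variance, colour = batch)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(title = paste(variant, "- gene mean vs variance"),
                    x = "gene mean", y = "gene variance") +
      ggplot2::theme_minimal(),
    path_of("mean_variance"))

  if (is.null(embedding)) embedding <- ds$embeddings$pca
  n <- n_obs(ds)
  set.seed(seed)
  keep <- if (n > max_points) sort(sample(n, max_points)) else seq_len(n)
  if (!is.null(embedding) && ncol(embedding) >= 2L) {
    ed <- data.frame(PC1 = embedding[keep, 1], PC2 = embedding[keep, 2],
                     batch = ds$batch[keep])
    scatter <- ggplot2::ggplot(ed, ggplot2::aes(PC1, PC2, colour = batch)) +
      ggplot2::geom_point(size = 0.5, alpha = 0.6) +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "bottom")
    topd <- ggplot2::ggplot(ed, ggplot2::aes(PC1, colour = batch)) +
      ggplot2::geom_density(show.legend = FALSE) + ggplot2::theme_void()
    rightd <- ggplot2::ggplot(ed, ggplot2::aes(PC2, colour = batch)) +
      ggplot2::geom_density(show.legend = FALSE) +
      ggplot2::coord_flip() + ggplot2::theme_void()
    joint <- topd + patchwork::plot_spacer() + scatter + rightd +
      patchwork::plot_layout(ncol = 2, widths = c(4, 1), heights = c(1, 4)) +
      patchwork::plot_annotation(title = paste(variant, "- joint embedding plot"))
    files["joint_pca"] <- save_panel(joint, path_of("joint_pca"))
  } else {
    files["joint_pca"] <- placeholder_panel(path_of("joint_pca"),
                                            "embedding unavailable")
  }

  um <- NULL
  if (identical(variant, "Raw") && !is.null(ds$embeddings$umap)) {
    um <- ds$embeddings$umap
  } else if (!is.null(embedding) && ncol(embedding) >= 2L &&
             n > 16L) {
    set.seed(seed)
    um <- uwot::umap(embedding, n_neighbors = min(15L, n - 1L),
                     n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  }
  if (!is.null(um)) {
    ud <- data.frame(x = um[keep, 1], y = um[keep, 2], batch = ds$batch[keep])
    files["umap"] <- save_panel(
      ggplot2::ggplot(ud, ggplot2::aes(x, y, colour = batch)) +
        ggplot2::geom_point(size = 0.5, alpha = 0.6) +
        ggplot2::labs(title = paste(variant, "- UMAP"), x = "UMAP1", y = "UMAP2") +
        ggplot2::theme_minimal(),
      path_of("umap"))
  } else {
    files["umap"] <- placeholder_panel(path_of("umap"), "UMAP unavailable")
  }

  qq_pairs <- 0L
  qqd <- NULL
  if (multi) {
    lv <- levels(ds$batch)
    qq <- list()
    probs <- seq(0.01, 0.99, by = 0.01)
    for (i in seq_len(length(lv) - 1L)) {
      for (j in seq.int(i + 1L, length(lv))) {
        qq[[length(qq) + 1L]] <- data.frame(
          qx = stats::quantile(totals[ds$batch == lv[i]], probs, names = FALSE),
          qy = stats::quantile(totals[ds$batch == lv[j]], probs, names = FALSE),
          pair = paste(lv[i], "vs", lv[j]))
      }
    }
    qqd <- do.call(rbind, qq)
    qq_pairs <- length(qq)
    files["qq"] <- save_panel(
      ggplot2::ggplot(qqd, ggplot2::aes(qx, qy)) +
        ggplot2::geom_point(size = 0.7) +
        ggplot2::geom_abline(linetype = 2, colour = "grey40") +
        ggplot2::facet_wrap(~pair) +
        ggplot2::labs(title = paste(variant, "- pairwise Q-Q of total counts"),
                      x = "quantiles", y = "quantiles") +
        ggplot2::theme_minimal(),
      path_of("qq"))
  } else {
    files["qq"] <- placeholder_panel(path_of("qq"),
                                     "single batch: pairwise Q-Q skipped")
  }
  list(files = files, qq_pairs = qq_pairs, qq = qqd)
}

fmt4 <- function(x) formatC(x, format = "f", digits = 4)

html_table <- function(header, rows) {
  cells <- vapply(rows, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>",
         "<tr>", paste0("<th>", header, "</th>", collapse = ""), "</tr>",
         paste0(cells, collapse = ""), "</table>")
}

html_page <- function(title, body, nav = TRUE) {
  paste0("<!DOCTYPE html><html><head><meta charset='utf-8'><title>", title,
         "</title></head><body>",
         if (nav) "<p><a href='index.html'>&#8592; Back to main page</a></p>" else "",
         "<h1>", title, "</h1>", body, "</body></html>")
}

metric_table_html <- function(v, n_batch, n_sample, types_source) {
  paste0(
    "<h2>Batch/domain estimate score</h2>",
    html_table(c("n_batch", "n_sample", "Train size", "Accept rate"),
               list(c(n_batch, n_sample, v$classifier$train_size,
                      fmt4(v$classifier$accept_rate)))),
    "<h2>k-BET score</h2>",
    html_table(c("chi mean", "95% p value", "Accept rate", "Reject rate"),
               list(fmt4(c(v$kbet$chi_mean, v$kbet$p_summary,
                           v$kbet$accept_rate, v$kbet$reject_rate)))),
    "<h2>Local inverse Simpson&#8217;s index</h2>",
    html_table(c("iLISI", "cLISI", "F1 score"),
               list(fmt4(c(v$lisi$iLISI, v$lisi$cLISI, v$lisi$f1)))),
    "<h2>Silhouette score</h2>",
    html_table(c("iSS", "cSS", "F1 score"),
               list(fmt4(c(v$silhouette$iSS, v$silhouette$cSS, v$silhouette$f1)))),
    "<p>Type-based metrics use labels from: ", types_source, ".</p>")
}

figures_html <- function(files) {
  paste0("<h2>Figures</h2>",
         paste0("<p><img src='", basename(files), "' width='600'></p>",
                collapse = ""))
}

#' Render the multi-page HTML report
#'
#' Writes `index.html` (summary grid, conclusion, navigation), `raw.html`
#' (statistical tables, metric tables, panels) and one page per correction
#' method into `outdir`. All asset links are relative so the directory opens
#' offline.
#'
#' @param summary a `BenchmarkSummary` from [run_benchmark()].
#' @param stats_bundle a `StatTestBundle` from [stat_test_battery()].
#' @param ds the evaluated [IntegratedDataset].
#' @param outdir output directory.
#' @param config the [batcheval_config()] used (seeds for figure sampling).
#' @return `outdir`, invisibly.
#' @export
render_report <- function(summary, stats_bundle, ds, outdir,
                          config = batcheval_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  variants <- summary$variants
  k <- nlevels(ds$batch)
  n <- n_obs(ds)

  # main page: Table-5-shaped grid
  grid_rows <- lapply(rownames(summary$table), function(rn) {
    c(rn, fmt4(as.numeric(summary$table[rn, ])))
  })
  page_link <- function(nm) {
    f <- if (nm == "Raw") "raw.html" else paste0("method_", slugify(nm), ".html")
    paste0("<a href='", f, "'>", nm, "</a>")
  }
  body <- paste0(
    "<p>", n, " observations, ", ncol(ds$matrix), " genes, ", k, " batches.</p>",
    html_table(c("", names(summary$table)), grid_rows),
    "<p><b>Conclusion</b>: ", summary$conclusion, "</p>",
    if (length(summary$failed))
      paste0("<p>Failed methods: ",
             paste(names(summary$failed), collapse = ", "), "</p>") else "",
    "<h2>Detailed pages</h2><ul>",
    paste0("<li>", vapply(names(variants), page_link, character(1)), "</li>",
           collapse = ""),
    "</ul><p>Full-precision values: <a href='metrics.json'>metrics.json</a></p>")
  writeLines(html_page("Batch-effect evaluation report", body, nav = FALSE),
             file.path(outdir, "index.html"))

  # raw page with the statistical battery
  an <- stats_bundle$anova
  ks_rows <- lapply(stats_bundle$ks, function(kr) {
    c(paste(kr$pair, collapse = "-"), kr$n_sample, fmt4(kr$stat), fmt4(kr$p_value))
  })
  assoc <- stats_bundle$association
  stat_html <- paste0(
    "<h2>Variation analysis</h2>",
    html_table(c("n_batch", "n_sample", "F", "p value",
                 paste0("F ref (", an$n_batch - 1, ", ", an$n_sample - an$n_batch, ")")),
               list(c(an$n_batch, an$n_sample, fmt4(an$F), fmt4(an$p_value),
                      fmt4(an$F_ref)))),
    "<h2>Kruskal&#8211;Wallis H</h2>",
    html_table(c("H", "p value"),
               list(fmt4(c(stats_bundle$kruskal$H, stats_bundle$kruskal$p_value)))),
    "<h2>K&#8211;S test</h2>",
    html_table(c("pair", "n_sample", "k-s stat", "p value"), ks_rows),
    "<h2>Cramer&#8217;s test</h2>",
    html_table(c("Pearson contingency coefficient", "Cramer's V coefficient"),
               list(fmt4(c(assoc$pearson_c, assoc$cramers_v)))),
    "<p>Condition labels: ", stats_bundle$condition_source, ".</p>")
  raw_figs <- render_figure_panels(ds, "Raw", outdir,
                                   seed = derive_seed(config$seed, 1L))
  writeLines(html_page("Raw integration evaluation",
                       paste0(stat_html,
                              metric_table_html(variants$Raw, k, n, summary$types_source),
                              figures_html(raw_figs$files))),
             file.path(outdir, "raw.html"))

  for (nm in setdiff(names(variants), "Raw")) {
    figs <- render_figure_panels(ds, nm, outdir,
                                 embedding = variants[[nm]]$embedding,
                                 seed = derive_seed(config$seed, 1L))
    writeLines(html_page(paste0("Method: ", nm),
                         paste0(metric_table_html(variants[[nm]], k, n, summary$types_source),
                                figures_html(figs$files))),
               file.path(outdir, paste0("method_", slugify(nm), ".html")))
  }
  invisible(outdir)
}
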