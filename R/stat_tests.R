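#' One-way ANOVA on per-observation total counts
#'
#' Variance analysis of library sizes grouped by batch, with the critical
#' value of the F distribution at the configured level reported alongside so
#' the report can show the observed statistic against its reference.
#'
#' @param totals numeric vector of per-observation total counts.
#' @param batch batch labels, same length.
#' @param alpha significance level for the reference quantile (default 0.05).
#' @return an `AnovaResult`: `n_batch`, `n_sample`, `F`, `p_value`, `F_ref`
#'   (the `1 - alpha` quantile of F with df `(k - 1, N - k)`).
#' @export
anova_total_counts <- function(totals, batch, alpha = 0.05) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least two batches")
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("every batch needs n_i >= 2 for the variance analysis; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  fit <- stats::oneway.test(totals ~ batch, var.equal = TRUE)
  k <- nlevels(batch)
  n <- length(totals)
  structure(list(
    n_batch = k, n_sample = n,
    F = unname(fit$statistic), p_value = unname(fit$p.value),
    F_ref = f_critical(k - 1L, n - k, 1 - alpha),
    alpha = alpha
  ), class = "AnovaResult")
}

#' Critical value of the F distribution
#'
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @param quantile probability in (0, 1); e.g. 0.95 for a 5\% test.
#' @return the `quantile` quantile of F(df1, df2).
#' @export
f_critical <- function(df1, df2, quantile = 0.95) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  stats::qf(quantile, df1, df2)
}

#' Kruskal-Wallis H statistic
#'
#' Rank-based test of whether the batches share one distribution:
#' \deqn{H = \frac{12}{N(N+1)} \sum_{i=1}^k \frac{R_i^2}{n_i} - 3(N+1)}
#' with average ranks for ties and the usual tie-correction divisor
#' \eqn{1 - \sum(t^3 - t) / (N^3 - N)}. The p-value uses the chi-square
#' approximation with `k - 1` degrees of freedom.
#'
#' @param values numeric vector (here: per-observation totals).
#' @param groups group labels, same length.
#' @return a `KWResult`: `H`, `p_value`, `N`, `k`, `n_i`, `R_i` (rank sums).
#' @export
kruskal_wallis_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  if (length(groups) != n) stop("values and groups differ in length")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (n < 3L) stop("need at least three observations")
  k <- nlevels(groups)
  if (length(unique(values)) == 1L) {
    return(structure(list(H = 0, p_value = 1, N = n, k = k,
                          n_i = as.integer(table(groups)),
                          R_i = tapply(rank(values), groups, sum)),
                     class = "KWResult"))
  }
  r <- rank(values)  # average ranks for ties
  n_i <- as.integer(table(groups))
  R_i <- as.numeric(tapply(r, groups, sum))
  H <- 12 / (n * (n + 1)) * sum(R_i^2 / n_i) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / correction
  structure(list(H = H, p_value = stats::pchisq(H, k - 1, lower.tail = FALSE),
                 N = n, k = k, n_i = n_i,
                 R_i = stats::setNames(R_i, levels(groups))),
            class = "KWResult")
}

#' Pairwise two-sample Kolmogorov-Smirnov tests
#'
#' For every unordered pair of batches, the supremum gap between the two
#' empirical CDFs of the per-observation totals,
#' \eqn{sup_x |F_1(x) - F_2(x)|}, with the two-sided asymptotic p-value.
#' Ties (common in count totals) are handled by the ECDF definition; the
#' exact-p tie warning from the underlying test is suppressed deliberately.
#'
#' @param totals numeric vector of per-observation totals.
#' @param batch batch labels, same length.
#' @return list of `KSResult`: `pair` (names), `n_sample` (pooled size),
#'   `stat`, `p_value`.
#' @export
ks_pairwise <- function(totals, batch) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least two batches")
  lv <- levels(batch)
  out <- list()
  for (i in seq_len(length(lv) - 1L)) {
    for (j in seq.int(i + 1L, length(lv))) {
      a <- totals[batch == lv[i]]
      b <- totals[batch == lv[j]]
      kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
      out[[length(out) + 1L]] <- structure(
        list(pair = c(lv[i], lv[j]), n_sample = length(a) + length(b),
             stat = unname(kt$statistic), p_value = unname(kt$p.value)),
        class = "KSResult")
    }
  }
  out
}

#' Contingency association between a condition and batch
#'
#' Cross-tabulates an experimental-condition label against the batch label
#' and summarizes their association with the Pearson chi-square (no
#' continuity correction), the contingency coefficient
#' \eqn{C = \sqrt{\chi^2 / (\chi^2 + N)}} and Cramer's V
#' \eqn{\phi_c = \sqrt{\chi^2 / (N (k - 1))}} where `k` is the smaller
#' dimension of the table.
#'
#' @param condition condition labels (>= 2 levels).
#' @param batch batch labels (>= 2 levels), same length.
#' @return an `AssociationResult`: `table`, `chi2`, `p_value`, `pearson_c`,
#'   `cramers_v`.
#' @export
contingency_association <- function(condition, batch) {
  condition <- factor(condition)
  batch <- factor(batch)
  if (length(condition) != length(batch)) stop("label vectors differ in length")
  if (nlevels(condition) < 2L || nlevels(batch) < 2L) {
    stop("Cramer's V is undefined when a dimension has a single level")
  }
  tab <- table(condition, batch)
  cramers_v_from_table(tab)
}

#' Cramer's V and the contingency coefficient from a count table
#' @param tab contingency table (matrix of counts), both dimensions >= 2.
#' @return an `AssociationResult` (see [contingency_association()]).
#' @export
cramers_v_from_table <- function(tab) {
  tab <- as.table(as.matrix(tab))
  if (any(dim(tab) < 2L)) stop("Cramer's V is undefined when a dimension has a single level")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(ct$statistic)
  n <- sum(tab)
  k <- min(dim(tab))
  structure(list(
    table = tab, chi2 = chi2, p_value = unname(ct$p.value),
    pearson_c = sqrt(chi2 / (chi2 + n)),
    cramers_v = sqrt(chi2 / (n * (k - 1)))
  ), class = "AssociationResult")
}

#' Run the full statistical battery on a dataset
#'
#' ANOVA and Kruskal-Wallis on per-observation totals grouped by batch,
#' pairwise K-S tests, and the contingency association. When no condition
#' column is supplied the totals are binned into quartiles as a proxy
#' condition (flagged in the result).
#'
#' @param ds an [IntegratedDataset].
#' @param condition optional condition labels; default quartile bins of the
#'   totals.
#' @param alpha significance level.
#' @return a `StatTestBundle`: `anova`, `kruskal`, `ks` (list), `association`,
#'   `condition_source`.
#' @export
stat_test_battery <- function(ds, condition = NULL, alpha = 0.05) {
  totals <- per_cell_total_counts(ds)
  src <- "user"
  if (is.null(condition)) {
    condition <- cut(totals, stats::quantile(totals, probs = seq(0, 1, 0.25)),
                     include.lowest = TRUE,
                     labels = paste0("Q", 1:4))
    src <- "total-count quartiles (proxy)"
  }
  structure(list(
    anova = anova_total_counts(totals, ds$batch, alpha),
    kruskal = kruskal_wallis_h(totals, ds$batch),
    ks = ks_pairwise(totals, ds$batch),
    association = contingency_association(condition, ds$batch),
    condition_source = src
  ), class = "StatTestBundle")
}
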