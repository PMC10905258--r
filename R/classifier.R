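#' Domain classifier configuration
#'
#' Defaults: one hidden layer of 128 relu units, focal loss with
#' `alpha = 1`, `gamma = 2` (the usual focal-loss setting, down-weighting
#' easy examples so unbalanced batches do not dominate), plain minibatch SGD
#' with learning rate 0.01 for 100 epochs, a 70/30 stratified split.
#'
#' @param hidden_units hidden-layer width.
#' @param alpha,gamma focal-loss hyperparameters (`alpha > 0`, `gamma >= 0`).
#' @param learning_rate SGD step size.
#' @param epochs passes over the training split.
#' @param batch_size minibatch size.
#' @param train_fraction fraction of observations used for training, in (0,1).
#' @param seed seed controlling the split, initialization and shuffling.
#' @return a `ClassifierConfig` list.
#' @export
classifier_config <- function(hidden_units = 128, alpha = 1, gamma = 2,
                              learning_rate = 0.01, epochs = 100,
                              batch_size = 64, train_fraction = 0.7, seed = 0) {
  stopifnot(train_fraction > 0, train_fraction < 1, gamma >= 0, alpha > 0,
            hidden_units >= 1, epochs >= 1, learning_rate > 0)
  structure(list(hidden_units = as.integer(hidden_units), alpha = alpha,
                 gamma = gamma, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' Stratified train/test split
#'
#' Deterministic split preserving per-batch proportions. The training size is
#' exactly `floor(train_fraction * N)`; per-batch quotas are
#' `floor(train_fraction * n_i)` with the remainder distributed by largest
#' fractional part (ties to the earlier batch level).
#'
#' @param batch batch labels (each level needs >= 2 observations).
#' @param train_fraction fraction in (0, 1).
#' @param seed seed for the within-batch draw.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(batch, train_fraction = 0.7, seed = 0) {
  batch <- factor(batch)
  n <- length(batch)
  sizes <- as.integer(table(batch))
  if (any(sizes < 2L)) stop("every batch needs at least two observations to split")
  target <- floor(train_fraction * n)
  if (target < 1L || target >= n) stop("train_fraction leaves an empty train or test set")
  quota <- floor(train_fraction * sizes)
  rem <- target - sum(quota)
  if (rem > 0) {
    frac <- train_fraction * sizes - quota
    bump <- order(-frac, seq_along(sizes))[seq_len(rem)]
    quota[bump] <- quota[bump] + 1L
  }
  set.seed(seed)
  train <- integer(0)
  for (i in seq_along(levels(batch))) {
    idx <- which(batch == levels(batch)[i])
    train <- c(train, sort(sample(idx, quota[i])))
  }
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

#' Focal loss
#'
#' \deqn{-\alpha (1 - P_t)^\gamma \log(P_t)}
#' where `P_t` is the predicted probability of the true class. With
#' `gamma = 0`, `alpha = 1` this reduces to cross-entropy. Vectorized inputs
#' are averaged. Probabilities are clamped at 1e-12 from below.
#'
#' @param prob_true_class probability (or vector of probabilities) in (0, 1].
#' @param alpha,gamma focal-loss hyperparameters.
#' @return mean focal loss (scalar).
#' @export
focal_loss <- function(prob_true_class, alpha = 1, gamma = 2) {
  p <- pmax(prob_true_class, 1e-12)
  mean(-alpha * (1 - p)^gamma * log(p))
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Gradient of the mean focal loss w.r.t. the logits of one minibatch.
# d/dp_t of -a(1-p)^g log p is a(g(1-p)^(g-1) log p - (1-p)^g / p); chain
# through softmax: dL/dz_j = g_t * p_t * (1[j = t] - p_j).
focal_grad_logits <- function(P, y, alpha, gamma) {
  m <- nrow(P)
  pt <- pmin(pmax(P[cbind(seq_len(m), y)], 1e-12), 1 - 1e-12)
  u <- 1 - pt
  gpt <- alpha * (gamma * u^pmax(gamma - 1, 0) * log(pt) - u^gamma / pt)
  if (gamma > 0 && gamma < 1) gpt <- alpha * (gamma * pmax(u, 1e-12)^(gamma - 1) * log(pt) - u^gamma / pt)
  dZ <- -P * (gpt * pt)
  dZ[cbind(seq_len(m), y)] <- dZ[cbind(seq_len(m), y)] + gpt * pt
  dZ / m
}

#' Fit the batch/domain classifier on a feature matrix
#'
#' One relu hidden layer plus a linear softmax head over the `k` batches,
#' trained with minibatch SGD on the focal loss. Held-out accuracy on the
#' stratified test split is the domain accuracy; `accept_rate = 1 -
#' domain_acc` is high when the batches are statistically indistinguishable.
#'
#' @param x numeric feature matrix, observations x features.
#' @param batch batch labels, length `nrow(x)`, >= 2 levels.
#' @param config a [classifier_config()].
#' @return a `ClassifierResult`: `n_batch`, `n_sample`, `train_size`,
#'   `domain_acc`, `accept_rate`, `loss_history` (mean focal loss per epoch),
#'   `model` (weights), `split`.
#' @export
classifier_fit <- function(x, batch, config = classifier_config()) {
  x <- as.matrix(x)
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least two batches to classify")
  n <- nrow(x)
  d <- ncol(x)
  k <- nlevels(batch)
  h <- config$hidden_units
  y <- as.integer(batch)

  split <- stratified_split(batch, config$train_fraction, config$seed)
  # standardize features on the training split: keeps the softmax away from
  # saturation at initialization whatever the feature scale (genes vs PCA)
  mu <- colMeans(x[split$train, , drop = FALSE])
  sdv <- apply(x[split$train, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]

  set.seed(config$seed + 1L)
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
  b2 <- numeric(k)

  ntr <- nrow(xtr)
  bs <- min(config$batch_size, ntr)
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(ntr)
    losses <- numeric(0)
    for (start in seq(1L, ntr, by = bs)) {
      take <- ord[start:min(start + bs - 1L, ntr)]
      xb <- xtr[take, , drop = FALSE]
      yb <- ytr[take]
      Hc <- relu(sweep(xb %*% W1, 2, b1, `+`))
      P <- softmax_rows(sweep(Hc %*% W2, 2, b2, `+`))
      pt <- P[cbind(seq_along(yb), yb)]
      losses <- c(losses, focal_loss(pt, config$alpha, config$gamma))
      dZ <- focal_grad_logits(P, yb, config$alpha, config$gamma)
      dW2 <- crossprod(Hc, dZ)
      db2 <- colSums(dZ)
      dH <- dZ %*% t(W2)
      dH[Hc <= 0] <- 0
      dW1 <- crossprod(xb, dH)
      db1 <- colSums(dH)
      W2 <- W2 - config$learning_rate * dW2
      b2 <- b2 - config$learning_rate * db2
      W1 <- W1 - config$learning_rate * dW1
      b1 <- b1 - config$learning_rate * db1
    }
    loss_history[epoch] <- mean(losses)
    if (!is.finite(loss_history[epoch])) {
      stop("non-finite focal loss at epoch ", epoch,
           " (learning rate ", config$learning_rate, ", ", d, " features); ",
           "reduce the learning rate or switch to pca features")
    }
  }

  xte <- x[split$test, , drop = FALSE]
  Hc <- relu(sweep(xte %*% W1, 2, b1, `+`))
  P <- softmax_rows(sweep(Hc %*% W2, 2, b2, `+`))
  pred <- max.col(P, ties.method = "first")
  acc <- mean(pred == y[split$test])

  structure(list(
    n_batch = k, n_sample = n, train_size = length(split$train),
    domain_acc = acc, accept_rate = 1 - acc,
    loss_history = loss_history,
    model = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(batch)),
    split = split, config = config
  ), class = "ClassifierResult")
}

#' Train the domain classifier on a dataset
#'
#' @param ds an [IntegratedDataset].
#' @param features `"normalized"` (gene vectors after [normalize_dataset()],
#'   the default) or `"pca"` (faster; requires [pca_embed()]).
#' @param config a [classifier_config()].
#' @return a `ClassifierResult` (see [classifier_fit()]).
#' @export
train_domain_classifier <- function(ds, features = c("normalized", "pca"),
                                    config = classifier_config()) {
  features <- match.arg(features)
  x <- if (features == "normalized") {
    if (is.null(ds$layers$normalized)) stop("normalized layer missing; run normalize_dataset() first")
    ds$layers$normalized
  } else {
    if (is.null(ds$embeddings$pca)) stop("pca embedding missing; run pca_embed() first")
    ds$embeddings$pca
  }
  classifier_fit(x, ds$batch, config)
}
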