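#' Fitness-evaluation settings
#'
#' Controls the wrapper evaluator that scores candidate feature subsets.
#' The fitness of a subset with cross-validated error `Er` and `p` of `q`
#' features selected is `omega * Er + (1 - omega) * p / q` (lower is
#' better); affinity, where the immune loop ranks antibodies, is its
#' negation.
#'
#' @param omega Weight on the error term, in (0,1). Default 0.99, putting
#'   almost all weight on accuracy while still breaking ties toward
#'   smaller subsets.
#' @param knn_k Neighbour count for the KNN evaluator (default 5); capped
#'   at the training-fold size.
#' @param cv_folds Stratified cross-validation folds (default 5). When
#'   any class has fewer members than `cv_folds`, evaluation falls back to
#'   leave-one-out.
#' @param standardize Z-score features using training-fold statistics
#'   before computing distances? Default `FALSE` (raw expression values).
#' @param seed Integer seed that fixes the fold assignment.
#'
#' @return A list of class `fitness_config`.
#' @export
fitness_config <- function(omega = 0.99, knn_k = 5, cv_folds = 5,
                           standardize = FALSE, seed = 1L) {
  stopifnot(omega > 0, omega < 1, knn_k >= 1, cv_folds >= 2)
  structure(list(omega = omega, knn_k = as.integer(knn_k),
                 cv_folds = as.integer(cv_folds),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "fitness_config")
}

#' Subset-size-penalised fitness
#'
#' `omega * error_rate + (1 - omega) * p / q`. Strictly increasing in both
#' the error rate and the subset size, and confined to \[0,1\] whenever
#' the error rate is.
#'
#' @param error_rate Cross-validated misclassification fraction in \[0,1\].
#' @param p Number of selected features (>= 1).
#' @param q Total number of features in the evaluated space (> 0).
#' @param omega Weight in (0,1); see [fitness_config()].
#' @return The scalar fitness; lower is better.
#' @export
fitness <- function(error_rate, p, q, omega = 0.99) {
  stopifnot(q > 0, p >= 1, p <= q, error_rate >= 0, error_rate <= 1)
  omega * error_rate + (1 - omega) * p / q
}

# Stratified fold ids, deterministic in (labels, cv_folds, seed).
# Samples are taken in sorted-sample-id order within class, so the
# assignment is invariant to permutations of the row order.
assign_folds <- function(labels, sample_ids, cv_folds, seed) {
  n <- length(labels)
  if (min(tabulate(labels)) < cv_folds) {
    return(seq_len(n))  # leave-one-out fallback for tiny classes
  }
  fold <- integer(n)
  withr::with_seed(seed, {
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      idx <- idx[order(sample_ids[idx], method = "radix")]
      fold[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
  })
  fold
}

# Majority-vote KNN prediction for one test block against one training
# block. Vote ties break toward the smallest class label (factor levels
# are sorted), so evaluation is fully deterministic.
knn_predict <- function(train_x, train_y, test_x, k, n_levels) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  pred <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nb <- train_y[order(d2[i, ], method = "radix")[seq_len(k)]]
    votes <- tabulate(nb, nbins = n_levels)
    pred[i] <- which.max(votes)  # first max = smallest label
  }
  pred
}

#' KNN cross-validation error of a feature subset
#'
#' Estimates the misclassification rate of a k-nearest-neighbour
#' classifier (Euclidean distance, majority vote, ties to the smallest
#' class label) restricted to the masked feature columns, by stratified
#' `cv_folds`-fold cross-validation. Fold assignment is derived from
#' `config$seed`, so repeated calls with the same mask are identical.
#' If any class is smaller than `cv_folds` the evaluator falls back to
#' leave-one-out. With `standardize` set, columns are z-scored using
#' training-fold statistics only.
#'
#' @param data A [labeled_dataset()] or data frame with a label column.
#' @param feature_mask Binary (0/1 or logical) vector over the dataset's
#'   features with at least one active entry.
#' @param config A [fitness_config()].
#' @param label_column Label column name when `data` is a data frame.
#' @param fold_ids Optional precomputed fold assignment (internal reuse).
#'
#' @return Mean per-fold misclassification fraction, in \[0,1\].
#' @export
knn_cv_error <- function(data, feature_mask, config = fitness_config(),
                         label_column = "class", fold_ids = NULL) {
  d <- as_labeled_dataset(data, label_column)
  mask <- as.logical(feature_mask)
  stopifnot(length(mask) == d$q)
  if (!any(mask)) abort("feature mask has no active features")
  x <- d$x[, mask, drop = FALSE]
  y <- as.integer(d$labels)
  if (is.null(fold_ids)) {
    fold_ids <- assign_folds(d$labels, d$sample_ids, config$cv_folds, config$seed)
  }
  errs <- vapply(sort(unique(fold_ids)), function(f) {
    te <- fold_ids == f
    tr_x <- x[!te, , drop = FALSE]
    te_x <- x[te, , drop = FALSE]
    if (config$standardize) {
      mu <- colMeans(tr_x)
      s <- apply(tr_x, 2, stats::sd)
      s[!is.finite(s) | s < 1e-12] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, s, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, s, "/")
    }
    pred <- knn_predict(tr_x, y[!te], te_x, config$knn_k, d$c)
    mean(pred != y[te])
  }, numeric(1))
  mean(errs)
}

# Evaluate one antibody (binary code over the filtered space) against the
# dataset, via the memoising cache. Returns list(fitness, error_rate, p, q).
evaluate_antibody <- function(code, dataset, config, cache, fold_ids = NULL) {
  key <- paste(which(code > 0), collapse = ",")
  hit <- cache$store[[key]]
  if (!is.null(hit)) return(hit)
  er <- knn_cv_error(dataset, code, config, fold_ids = fold_ids)
  p <- sum(code > 0)
  res <- list(fitness = fitness(er, p, dataset$q, config$omega),
              error_rate = er, p = p, q = dataset$q)
  cache$store[[key]] <- res
  cache$n_evals <- cache$n_evals + 1L
  res
}

new_fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$n_evals <- 0L
  e
}
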