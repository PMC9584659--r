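#' Fisher scores of every feature
#'
#' Stage-1 filter statistic. For feature `i` with overall mean `u_i`,
#' per-class means `u_ki`, per-class population variances `s2_ki` and
#' class sizes `n_k`, the Fisher score is
#'
#' \deqn{F_i = \frac{\sum_k n_k (u_{ki} - u_i)^2}{\sum_k n_k s^2_{ki}}}
#'
#' the ratio of between-class to within-class dispersion: large when a
#' feature separates the classes well. Variances are population variances
#' (divide by `n_k`), so singleton classes are tolerated. The denominator
#' is floored at `1e-12` to keep scores finite and totally ordered: a
#' feature with distinct class means but zero within-class variance gets
#' a huge (finite) score, and a constant feature scores exactly 0.
#'
#' @param data A [labeled_dataset()] or a data frame with a label column.
#' @param label_column Label column name when `data` is a data frame.
#'
#' @return An object of class `fisher_scores`: list with `scores` (length
#'   `q`), `feature_names`, `class_counts`, `class_means` and
#'   `class_variances` (`c x q` matrices), `overall_means`, `n_classes`.
#'   Use [tidy()] for a ranked tibble.
#' @seealso [select_top_k()]
#' @export
fisher_scores <- function(data, label_column = "class") {
  d <- as_labeled_dataset(data, label_column)
  if (d$n == 0 || d$q == 0) abort("empty dataset")
  lev <- levels(d$labels)
  n_k <- tabulate(d$labels, nbins = length(lev))
  cm <- matrix(0, length(lev), d$q, dimnames = list(lev, d$feature_names))
  cv <- cm
  for (k in seq_along(lev)) {
    xk <- d$x[d$labels == lev[k], , drop = FALSE]
    cm[k, ] <- colMeans(xk)
    # population variance: mean of squares minus squared mean
    cv[k, ] <- colMeans(xk^2) - cm[k, ]^2
  }
  u <- colMeans(d$x)
  between <- colSums(n_k * sweep(cm, 2, u)^2)
  within <- colSums(n_k * cv)
  scores <- between / pmax(within, 1e-12)
  structure(
    list(scores = unname(scores), feature_names = d$feature_names,
         class_counts = setNames(n_k, lev), class_means = cm,
         class_variances = cv, overall_means = unname(u),
         n_classes = length(lev)),
    class = "fisher_scores"
  )
}

#' @export
print.fisher_scores <- function(x, ...) {
  cat(sprintf("<fisher_scores> %d features, %d classes; top score %.4g\n",
              length(x$scores), x$n_classes, max(x$scores)))
  invisible(x)
}

#' @rdname fisher_scores
#' @param x A `fisher_scores` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fisher_scores <- function(x, ...) {
  ord <- order(-x$scores, seq_along(x$scores), method = "radix")
  tibble::tibble(
    feature = x$feature_names[ord],
    index = ord,
    score = x$scores[ord],
    rank = seq_along(ord)
  )
}

#' Retain the top-scoring candidate features
#'
#' Keeps the `min(fisher_k, q)` features with the highest Fisher scores,
#' breaking ties at the cut rank by ascending original column index so the
#' result is deterministic. The retained space is what the immune search
#' explores.
#'
#' @param scores A [fisher_scores()] object for `data`.
#' @param data The source [labeled_dataset()] (or data frame).
#' @param fisher_k Number of features to retain (default 200).
#' @param label_column Label column name when `data` is a data frame.
#'
#' @return An object of class `filtered_dataset`: list with `dataset`
#'   (the restricted [labeled_dataset()]), `original_indices` (filtered
#'   column -> original column), and `fisher_scores` (the retained scores,
#'   non-increasing).
#' @export
select_top_k <- function(scores, data, fisher_k = 200, label_column = "class") {
  stopifnot(inherits(scores, "fisher_scores"), fisher_k >= 1)
  d <- as_labeled_dataset(data, label_column)
  stopifnot(length(scores$scores) == d$q)
  m <- min(as.integer(fisher_k), d$q)
  ord <- order(-scores$scores, seq_along(scores$scores), method = "radix")
  keep <- ord[seq_len(m)]
  structure(
    list(
      dataset = labeled_dataset(d$x[, keep, drop = FALSE], d$labels,
                                feature_names = d$feature_names[keep],
                                sample_ids = d$sample_ids),
      original_indices = keep,
      fisher_scores = scores$scores[keep],
      q_original = d$q
    ),
    class = "filtered_dataset"
  )
}

#' @export
print.filtered_dataset <- function(x, ...) {
  cat(sprintf("<filtered_dataset> %d of %d features retained (top Fisher score %.4g)\n",
              length(x$original_indices), x$q_original, max(x$fisher_scores)))
  invisible(x)
}

#' Fisher-threshold sweep on a dataset
#'
#' Evaluates KNN cross-validation accuracy of the top-`k` Fisher features
#' for a grid of thresholds, mirroring the oscillating
#' accuracy-vs-threshold behaviour that motivates a second search stage.
#'
#' @param data A [labeled_dataset()] or data frame.
#' @param thresholds Integer vector of filter sizes to evaluate.
#' @param config A [fitness_config()].
#' @param label_column Label column name when `data` is a data frame.
#'
#' @return A tibble with columns `fisher_k`, `n_features`, `accuracy`.
#' @export
fisher_sweep <- function(data, thresholds = c(10, 25, 50, 100, 200),
                         config = fitness_config(), label_column = "class") {
  d <- as_labeled_dataset(data, label_column)
  fs <- fisher_scores(d)
  rows <- lapply(thresholds, function(k) {
    fd <- select_top_k(fs, d, fisher_k = k)
    err <- knn_cv_error(fd$dataset, rep(1L, fd$dataset$q), config)
    tibble::tibble(fisher_k = k, n_features = fd$dataset$q, accuracy = 1 - err)
  })
  do.call(rbind, rows)
}
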