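#' @export
print.hfia_result <- function(x, ...) {
  cat("Hybrid immune feature selection\n")
  cat(sprintf("  selected %d of %d features (reduction rate %.2f%%)\n",
              x$n_selected, x$q, 100 * x$reduction_rate))
  cat(sprintf("  final CV accuracy %.4f (error %.4f), best fitness %.6f\n",
              x$final_accuracy, x$final_error_rate, x$best_fitness))
  cat(sprintf("  %d fitness evaluations over %d iterations, seed %d\n",
              x$n_evaluations, length(x$best_fitness_trajectory) - 1L,
              x$seed))
  if (x$n_selected <= 12) {
    cat("  features:", paste(x$selected_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the selected feature subset
#'
#' @param x An `hfia_result`.
#' @param ... Unused.
#' @return A tibble with one row per selected feature: `feature`,
#'   `index` (original column index).
#' @exportS3Method generics::tidy
tidy.hfia_result <- function(x, ...) {
  tibble::tibble(feature = as.character(x$selected_names),
                 index = as.integer(x$selected_features))
}

#' One-row summary of a selection run
#'
#' @param x An `hfia_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_selected`, `q`, `reduction_rate`,
#'   `final_accuracy`, `final_error_rate`, `best_fitness`,
#'   `n_evaluations`, `seed`.
#' @exportS3Method generics::glance
glance.hfia_result <- function(x, ...) {
  tibble::tibble(
    n_selected = x$n_selected, q = x$q,
    reduction_rate = x$reduction_rate,
    final_accuracy = x$final_accuracy,
    final_error_rate = x$final_error_rate,
    best_fitness = x$best_fitness,
    n_evaluations = x$n_evaluations,
    seed = x$seed
  )
}

#' Plot the best-fitness trajectory
#'
#' The best (lowest) fitness found at each iteration; non-increasing by
#' the elitism guarantee.
#'
#' @param object An `hfia_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hfia_result <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$best_fitness_trajectory) - 1L,
    best_fitness = object$best_fitness_trajectory
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step(colour = "#2b6cb0") +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = "Clonal-selection convergence") +
    ggplot2::theme_minimal()
}

#' Plot ranked Fisher scores
#'
#' Scree-style view of the ranked per-feature Fisher scores; the filter
#' keeps the left-most `fisher_k` features.
#'
#' @param object A `fisher_scores` object.
#' @param top Show only the `top` highest-ranked features (default 500).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fisher_scores <- function(object, top = 500, ...) {
  df <- head(tidy(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "#2f855a") +
    ggplot2::labs(x = "Rank", y = "Fisher score",
                  title = "Ranked Fisher scores") +
    ggplot2::theme_minimal()
}
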