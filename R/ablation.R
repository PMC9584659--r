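#' Ablation of the two pipeline stages
#'
#' Evaluates KNN cross-validation accuracy under three conditions on the
#' same dataset: `Full` (every feature, no selection), `Fisher`
#' (filter stage only, the top `fisher_k` features), and `HFIA` (the
#' complete filter + immune-search pipeline). Reported subset sizes are
#' `q`, `min(fisher_k, q)` and the searched subset size respectively.
#'
#' @param data A [labeled_dataset()] or data frame with a label column.
#' @param config An [hfia_config()].
#' @param label_column Label column name when `data` is a data frame.
#' @return A three-row tibble with columns `condition`, `n_features`,
#'   `accuracy`.
#' @export
hfia_ablation <- function(data, config = hfia_config(), label_column = "class") {
  d <- as_labeled_dataset(data, label_column)
  fcfg <- config$fitness_config
  full_err <- knn_cv_error(d, rep(1L, d$q), fcfg)
  fd <- select_top_k(fisher_scores(d), d, config$fisher_k)
  fisher_err <- knn_cv_error(fd$dataset, rep(1L, fd$dataset$q), fcfg)
  res <- run_hfia(d, config)
  tibble::tibble(
    condition = c("Full", "Fisher", "HFIA"),
    n_features = c(d$q, fd$dataset$q, res$n_selected),
    accuracy = c(1 - full_err, 1 - fisher_err, res$final_accuracy)
  )
}
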