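# Generic clonal-selection loop over an arbitrary evaluator.
# `eval_fn(code)` must return list(fitness=, error_rate=, p=, q=).
# Assumes the caller has seeded the RNG stream.
search_core <- function(m, eval_fn, config, verbose = FALSE) {
  score <- function(ab) {
    if (is.na(ab$fitness)) {
      res <- eval_fn(ab$code)
      ab$fitness <- res$fitness
      ab$error_rate <- res$error_rate %||% NA_real_
    }
    ab
  }
  truncate_pool <- function(pool) {
    fit <- vapply(pool, `[[`, numeric(1), "fitness")
    p <- vapply(pool, `[[`, numeric(1), "p")
    pool[order(fit, p, seq_along(pool), method = "radix")[seq_len(config$N)]]
  }

  pop <- lapply(init_population(m, config), score)
  pop <- truncate_pool(pop)  # sort: pop[[1]] is the incumbent best
  traj <- numeric(config$Tmax + 1)
  traj[1] <- pop[[1]]$fitness
  best_improved <- TRUE

  for (t in seq_len(config$Tmax)) {
    state <- schedule(t, config$Tmax)
    state$best_improved <- best_improved
    mutated <- lethal_mutation(clone_antibodies(select_elites(pop, config),
                                                config), state)
    fresh <- lapply(seq_len(config$N), function(i) {
      new_antibody(cauchy_code(m, config$eta + state$theta))
    })
    pool <- lapply(c(pop, mutated, fresh), score)
    pop <- truncate_pool(pool)
    traj[t + 1] <- pop[[1]]$fitness
    best_improved <- traj[t + 1] < traj[t]
    if (verbose) {
      message(sprintf("iter %3d: best fitness %.6f, subset size %d",
                      t, traj[t + 1], pop[[1]]$p))
    }
  }
  list(best = pop[[1]], trajectory = traj, population = pop)
}

#' Run the hybrid immune feature selection
#'
#' The full two-stage pipeline. Stage 1 scores every feature with the
#' Fisher criterion and keeps the top `min(fisher_k, q)` candidates.
#' Stage 2 runs the improved clonal-selection loop over binary feature
#' masks of that candidate space: Cauchy-initialised antibodies are
#' scored by KNN cross-validation fitness ([fitness_config()]), elites
#' are cloned in proportion to affinity rank, clones undergo conditional
#' lethal mutation (gene counts only fall while the best fitness keeps
#' improving), and an incremental update injects progressively sparser
#' fresh antibodies before elitist truncation back to `N`. The best
#' antibody's active loci are mapped back to original feature indices.
#'
#' A fixed `config$seed` makes the whole run bit-reproducible. The final
#' subset is re-evaluated on freshly seeded cross-validation folds, so
#' the reported accuracy is not the one the search optimised against.
#'
#' @param data A [labeled_dataset()], or a data frame with a label column.
#' @param config An [hfia_config()].
#' @param label_column Label column name when `data` is a data frame.
#' @param verbose Log per-generation best fitness and subset size?
#'
#' @return An object of class `hfia_result` with elements
#'   `selected_features` (original column indices, ascending),
#'   `selected_names`, `n_selected`, `reduction_rate`
#'   (`1 - n_selected/q`), `final_error_rate`, `final_accuracy`,
#'   `best_fitness`, `best_fitness_trajectory` (length `Tmax + 1`,
#'   non-increasing), `n_evaluations`, `config_echo`, and `seed`.
#'   [tidy()], [glance()] and [autoplot()] methods are provided.
#'
#' @examples
#' \donttest{
#' synth <- make_dataset(synthetic_spec(n_samples = 60, n_features = 300,
#'                                      n_informative = 8, seed = 7))
#' res <- run_hfia(synth$dataset, hfia_config(Tmax = 10, fisher_k = 50, seed = 1))
#' glance(res)
#' }
#' @export
run_hfia <- function(data, config = hfia_config(), label_column = "class",
                     verbose = FALSE) {
  d <- as_labeled_dataset(data, label_column)
  fs <- fisher_scores(d)
  fd <- select_top_k(fs, d, config$fisher_k)
  m <- fd$dataset$q
  cache <- new_fitness_cache()
  fcfg <- config$fitness_config
  fold_ids <- assign_folds(fd$dataset$labels, fd$dataset$sample_ids,
                           fcfg$cv_folds, fcfg$seed)
  eval_fn <- function(code) {
    evaluate_antibody(code, fd$dataset, fcfg, cache, fold_ids)
  }
  core <- withr::with_seed(config$seed,
                           search_core(m, eval_fn, config, verbose = verbose))
  best <- core$best
  sel <- sort(fd$original_indices[best$code == 1L])

  final_cfg <- fcfg
  final_cfg$seed <- offset_seed(config$seed, 2000L)
  final_err <- knn_cv_error(fd$dataset, best$code, final_cfg)

  new_hfia_result(
    selected_features = sel,
    selected_names = d$feature_names[sel],
    n_selected = length(sel),
    q = d$q,
    m = m,
    final_error_rate = final_err,
    best_fitness = best$fitness,
    trajectory = core$trajectory,
    n_evaluations = cache$n_evals,
    config = config
  )
}

new_hfia_result <- function(selected_features, selected_names, n_selected, q,
                            m, final_error_rate, best_fitness, trajectory,
                            n_evaluations, config) {
  structure(
    list(
      selected_features = as.integer(selected_features),
      selected_names = selected_names,
      n_selected = as.integer(n_selected),
      q = as.integer(q),
      m = as.integer(m),
      reduction_rate = 1 - n_selected / q,
      final_error_rate = final_error_rate,
      final_accuracy = 1 - final_error_rate,
      best_fitness = best_fitness,
      best_fitness_trajectory = trajectory,
      n_evaluations = as.integer(n_evaluations),
      config_echo = config_echo(config),
      seed = config$seed
    ),
    class = "hfia_result"
  )
}

config_echo <- function(config) {
  fc <- config$fitness_config
  list(N = config$N, c_r = config$c_r, Tmax = config$Tmax, eta = config$eta,
       beta = config$beta, fisher_k = config$fisher_k, seed = config$seed,
       omega = fc$omega, knn_k = fc$knn_k, cv_folds = fc$cv_folds,
       standardize = fc$standardize, fitness_seed = fc$seed)
}

#' Search with a user-supplied fitness
#'
#' Runs the clonal-selection core over binary codes of length `m` with an
#' arbitrary deterministic evaluator instead of the KNN wrapper — useful
#' for calibration studies and optimality checks on small spaces where
#' the true optimum can be enumerated.
#'
#' @param m Code length.
#' @param eval_fn Function taking a 0/1 integer vector and returning the
#'   scalar fitness to minimise (must be deterministic).
#' @param config An [hfia_config()] (its `fitness_config` is ignored).
#' @return List with `best` (antibody), `best_fitness`, `trajectory`.
#' @export
hfia_search <- function(m, eval_fn, config = hfia_config()) {
  wrapped <- function(code) {
    list(fitness = eval_fn(code), error_rate = NA_real_,
         p = sum(code > 0), q = m)
  }
  core <- withr::with_seed(config$seed, search_core(m, wrapped, config))
  list(best = core$best, best_fitness = core$best$fitness,
       trajectory = core$trajectory)
}
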