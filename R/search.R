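#' Immune-search settings
#'
#' Configuration of the improved clonal-selection search. Defaults are
#' the experimental configuration of the method: 50 iterations, 10
#' antibodies, select rate 0.5, Cauchy activation threshold -0.2, fitness
#' weight 0.99 and a Fisher filter size of 200.
#'
#' @param N Population size (>= 2). Default 10.
#' @param c_r Select rate in (0,1\]: the elite pool holds
#'   `round(c_r * N)` antibodies. Default 0.5.
#' @param Tmax Number of iterations (>= 1). Default 50.
#' @param eta Cauchy activation threshold for initial antibodies: a locus
#'   is switched on when its standard-Cauchy draw exceeds `eta`. Default
#'   -0.2, giving an expected activation density of
#'   `1 - cauchy_cdf(-0.2)` (about 0.563).
#' @param beta Clone factor: the rank-`i` elite contributes
#'   `round(beta * N / i)` clones (at least 1, halves rounded away from
#'   zero). Default 1.
#' @param fisher_k Stage-1 filter size. Default 200.
#' @param fitness_config A [fitness_config()].
#' @param seed Master seed; every stochastic draw of the run derives from
#'   it, so a fixed seed gives a bit-identical result.
#'
#' @return A list of class `hfia_config`.
#' @export
hfia_config <- function(N = 10, c_r = 0.5, Tmax = 50, eta = -0.2, beta = 1,
                        fisher_k = 200, fitness_config = NULL, seed = 1L) {
  stopifnot(N >= 2, c_r > 0, c_r <= 1, Tmax >= 0, beta > 0, fisher_k >= 1)
  if (is.null(fitness_config)) {
    fitness_config <- hfia::fitness_config(seed = offset_seed(seed, 1000L))
  }
  n_sel <- max(1L, round_half_up(c_r * N))
  structure(list(N = as.integer(N), c_r = c_r, Tmax = as.integer(Tmax),
                 eta = eta, beta = beta, fisher_k = as.integer(fisher_k),
                 n_select = n_sel, fitness_config = fitness_config,
                 seed = as.integer(seed)),
            class = "hfia_config")
}

# round halves away from zero (base round() rounds halves to even)
round_half_up <- function(x) floor(x + 0.5)

offset_seed <- function(seed, k) as.integer((as.double(seed) + k) %% 2147483647)

#' Adaptive schedule factors
#'
#' At iteration `t` of `Tmax`, the acceleration factor
#' `delta = 0.5 - t/Tmax` (from 0.5 down to -0.5) sets the
#' mutation-locus threshold — as it falls, more loci mutate — and the
#' diversity factor `theta = t/Tmax` (from 0 up to 1) raises the
#' activation threshold of fresh antibodies, making newcomers sparser as
#' the run progresses.
#'
#' @param t Current iteration, `0 <= t <= Tmax`.
#' @param Tmax Total iterations (>= 1).
#' @return A list of class `schedule_state` with `t`, `Tmax`, `delta`,
#'   `theta`, and a `best_improved` flag (filled in by the search loop).
#' @export
schedule <- function(t, Tmax) {
  stopifnot(Tmax >= 1, t >= 0, t <= Tmax)
  structure(list(t = t, Tmax = Tmax, delta = 0.5 - t / Tmax,
                 theta = t / Tmax, best_improved = NA),
            class = "schedule_state")
}

# -- antibodies ---------------------------------------------------------

new_antibody <- function(code) {
  list(code = code, fitness = NA_real_, error_rate = NA_real_,
       p = sum(code > 0L))
}

# activate one uniformly random locus if the code is all-zero
repair_code <- function(code) {
  if (!any(code > 0L)) code[sample.int(length(code), 1L)] <- 1L
  code
}

# threshold rule shared by initialisation and the incremental update:
# locus on iff its standard-Cauchy draw exceeds `threshold`
cauchy_code <- function(m, threshold) {
  repair_code(as.integer(rcauchy(m) > threshold))
}

#' Initialise an antibody population
#'
#' Generates `N` binary antibodies of length `m`: each locus receives an
#' independent standard-Cauchy draw and is switched on when the draw
#' exceeds `config$eta`. All-zero antibodies are repaired by activating
#' one uniformly random locus. Draws come from the global RNG stream;
#' seed it (or call via [run_hfia()]) for reproducibility.
#'
#' @param m Length of the antibody code (filtered feature count).
#' @param config An [hfia_config()].
#' @return List of `N` antibodies (lists with `code`, `fitness`,
#'   `error_rate`, `p`).
#' @export
init_population <- function(m, config = hfia_config()) {
  stopifnot(m >= 1)
  lapply(seq_len(config$N), function(i) new_antibody(cauchy_code(m, config$eta)))
}

#' Select the elite pool
#'
#' The `round(c_r * N)` antibodies with lowest fitness (highest
#' affinity), in ascending fitness order. Ties break toward fewer active
#' genes, then earlier position in the population.
#'
#' @param population List of evaluated antibodies.
#' @param config An [hfia_config()].
#' @return The ordered elite list.
#' @export
select_elites <- function(population, config) {
  fit <- vapply(population, `[[`, numeric(1), "fitness")
  p <- vapply(population, `[[`, numeric(1), "p")
  ord <- order(fit, p, seq_along(population), method = "radix")
  population[ord[seq_len(min(config$n_select, length(population)))]]
}

#' Clone the elite pool
#'
#' The rank-`i` elite (1-based, best first) contributes
#' `round(beta * N / i)` independent copies (minimum 1, halves rounded
#' away from zero) — clone counts proportional to affinity rank, as in
#' classical clonal selection.
#'
#' @param elites Ordered elite list from [select_elites()].
#' @param config An [hfia_config()].
#' @return Flat list of clones; each is an independent copy.
#' @export
clone_antibodies <- function(elites, config) {
  stopifnot(length(elites) >= 1)
  out <- list()
  for (i in seq_along(elites)) {
    n_i <- max(1L, round_half_up(config$beta * config$N / i))
    out <- c(out, rep(elites[i], n_i))
  }
  out
}

#' Conditional lethal mutation
#'
#' Each locus of each clone receives an independent standard-Cauchy draw;
#' loci whose draw exceeds `state$delta` are the mutation loci (a smaller
#' `delta` recruits more loci). While the best fitness is still improving
#' (`state$best_improved`), mutation is *lethal*: active mutation loci
#' are deactivated and inactive ones left alone, so gene counts only
#' fall — a one-way pressure toward smaller feature subsets. On
#' stagnation the operator reverts to ordinary bit-flips to restore
#' exploration. All-zero results are repaired to one random active gene
#' and cached fitness is invalidated.
#'
#' @param clones List of clones from [clone_antibodies()].
#' @param state A [schedule()] state with `best_improved` set.
#' @return The mutated list.
#' @export
lethal_mutation <- function(clones, state) {
  lethal <- isTRUE(state$best_improved)
  lapply(clones, function(ab) {
    loci <- rcauchy(length(ab$code)) > state$delta
    code <- ab$code
    if (lethal) {
      code[loci & code == 1L] <- 0L
    } else {
      code[loci] <- 1L - code[loci]
    }
    new_antibody(repair_code(code))
  })
}

#' Incremental population update
#'
#' Generates `N` fresh antibodies by the Cauchy threshold rule at
#' activation threshold `eta + theta` — newcomers grow sparser as the run
#' progresses — evaluates every unevaluated antibody among
#' \{current population, mutated clones, newcomers\}, and keeps the `N`
#' fittest (ties: fewer genes, then earlier origin in that order). The
#' previous best is always retained or beaten: the best fitness never
#' increases.
#'
#' @param population Current evaluated population.
#' @param mutated Mutated clone list.
#' @param state A [schedule()] state (supplies `theta`).
#' @param dataset The filtered [labeled_dataset()] (evaluation space).
#' @param config An [hfia_config()].
#' @param cache Internal memoisation environment.
#' @param fold_ids Optional precomputed fold assignment.
#' @return The next population (length `N`).
#' @export
population_update <- function(population, mutated, state, dataset, config,
                              cache = new_fitness_cache(), fold_ids = NULL) {
  fresh <- lapply(seq_len(config$N), function(i) {
    new_antibody(cauchy_code(length(population[[1]]$code),
                             config$eta + state$theta))
  })
  pool <- c(population, mutated, fresh)
  pool <- lapply(pool, function(ab) {
    if (is.na(ab$fitness)) {
      res <- evaluate_antibody(ab$code, dataset, config$fitness_config,
                               cache, fold_ids)
      ab$fitness <- res$fitness
      ab$error_rate <- res$error_rate
    }
    ab
  })
  fit <- vapply(pool, `[[`, numeric(1), "fitness")
  p <- vapply(pool, `[[`, numeric(1), "p")
  ord <- order(fit, p, seq_along(pool), method = "radix")
  pool[ord[seq_len(config$N)]]
}
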