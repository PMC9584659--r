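test_that("schedule factors are the stated linear ramps", {
  expect_identical(schedule(0, 50)$delta, 0.5)
  expect_identical(schedule(50, 50)$delta, -0.5)
  expect_identical(schedule(25, 50)$delta, 0)
  expect_identical(schedule(25, 50)$theta, 0.5)
  expect_identical(schedule(0, 50)$theta, 0)
  expect_identical(schedule(50, 50)$theta, 1)
  for (t in 0:10) {
    s <- schedule(t, 10)
    expect_equal(s$delta, 0.5 - t / 10)
    expect_equal(s$theta, t / 10)
  }
  expect_error(schedule(11, 10))
})

test_that("initial antibodies have Cauchy-threshold density and no empty codes", {
  withr::local_seed(42)
  cfg <- hfia_config(N = 10)
  pop <- init_population(10000, cfg)
  expect_length(pop, 10)
  density <- mean(vapply(pop, function(ab) mean(ab$code), numeric(1)))
  expect_lt(abs(density - (1 - cauchy_cdf(-0.2))), 0.01)

  # extreme threshold: everything repaired to exactly one active locus
  sparse <- init_population(50, hfia_config(N = 6, eta = 1e6))
  expect_true(all(vapply(sparse, function(ab) sum(ab$code), numeric(1)) == 1))
})

test_that("elite selection takes the n lowest-fitness antibodies with stated ties", {
  mk <- function(fit, p) {
    ab <- hfia:::new_antibody(c(rep(1L, p), rep(0L, 10 - p)))
    ab$fitness <- fit
    ab
  }
  cfg <- hfia_config(N = 10, c_r = 0.5)
  expect_equal(cfg$n_select, 5L)

  withr::local_seed(3)
  pop <- lapply(runif(10), function(f) mk(f, sample(1:9, 1)))
  got <- select_elites(pop, cfg)
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  expect_equal(vapply(got, `[[`, numeric(1), "fitness"), sort(fit)[1:5])

  # equal fitness: fewest active genes wins
  tied <- list(mk(0.5, 3), mk(0.5, 1), mk(0.5, 2))
  best <- select_elites(tied, hfia_config(N = 2, c_r = 0.5))
  expect_equal(best[[1]]$p, 1)
})

test_that("clone counts follow round(beta*N/rank) and copies are independent", {
  mk <- function(fit) {
    ab <- hfia:::new_antibody(rep(1L, 4))
    ab$fitness <- fit
    ab
  }
  cfg <- hfia_config(N = 10, c_r = 0.5, beta = 1)
  elites <- lapply(c(0.1, 0.2, 0.3, 0.4, 0.5), mk)
  clones <- clone_antibodies(elites, cfg)
  counts <- table(vapply(clones, `[[`, numeric(1), "fitness"))
  expect_equal(as.integer(counts), c(10L, 5L, 3L, 3L, 2L))
  expect_length(clones, 23)

  single <- clone_antibodies(elites[1], cfg)
  expect_length(single, 10)

  clones[[1]]$code[1] <- 0L
  expect_equal(clones[[2]]$code[1], 1L)  # deep copy
})

test_that("lethal mode only removes genes; exploration mode flips", {
  withr::local_seed(9)
  full <- hfia:::new_antibody(rep(1L, 200))
  st <- schedule(10, 50)

  st$best_improved <- TRUE
  for (rep in 1:20) {
    mut <- lethal_mutation(list(full), st)[[1]]
    expect_lte(sum(mut$code), 200)
    expect_gte(sum(mut$code), 1)
    expect_true(is.na(mut$fitness))  # cache invalidated
  }

  # a very low threshold in exploration mode flips essentially every locus
  st$best_improved <- FALSE
  st$delta <- -1e9
  flipped <- lethal_mutation(list(full), st)[[1]]
  expect_equal(sum(flipped$code), 0 + 1)  # all off, then repaired to one

  mixed <- hfia:::new_antibody(rep(c(1L, 0L), 100))
  half <- lethal_mutation(list(mixed), st)[[1]]
  expect_equal(half$code, 1L - mixed$code)  # exact complement at delta -> -Inf
})

test_that("mutation-locus fraction tracks 1 - F(delta)", {
  withr::local_seed(14)
  full <- hfia:::new_antibody(rep(1L, 1e5))
  st <- schedule(0, 50)  # delta = 0.5
  st$best_improved <- TRUE
  mut <- lethal_mutation(list(full), st)[[1]]
  frac_removed <- 1 - mean(mut$code)
  expect_lt(abs(frac_removed - (1 - cauchy_cdf(0.5))), 0.01)
})

test_that("population update keeps N antibodies, elitism, and sparser newcomers", {
  withr::local_seed(6)
  d <- separated_clusters(n_per_class = 8, q = 12)
  cfg <- hfia_config(N = 8, Tmax = 10, fisher_k = 12,
                     fitness_config = fitness_config(seed = 2))
  cache <- hfia:::new_fitness_cache()
  pop <- lapply(init_population(12, cfg), function(ab) {
    res <- hfia:::evaluate_antibody(ab$code, d, cfg$fitness_config, cache)
    ab$fitness <- res$fitness
    ab$error_rate <- res$error_rate
    ab
  })
  best_before <- min(vapply(pop, `[[`, numeric(1), "fitness"))
  st <- schedule(5, 10)
  st$best_improved <- TRUE
  mutated <- lethal_mutation(clone_antibodies(select_elites(pop, cfg), cfg), st)
  nxt <- population_update(pop, mutated, st, d, cfg, cache)
  expect_length(nxt, 8)
  fits <- vapply(nxt, `[[`, numeric(1), "fitness")
  expect_true(all(is.finite(fits)))
  expect_lte(min(fits), best_before)
  expect_true(all(vapply(nxt, function(ab) sum(ab$code), numeric(1)) >= 1))

  # fresh antibodies at theta = 1 activate at threshold eta + 1
  withr::local_seed(91)
  codes <- replicate(300, hfia:::cauchy_code(100, -0.2 + 1))
  expect_lt(abs(mean(codes) - (1 - cauchy_cdf(0.8))), 0.02)
})
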