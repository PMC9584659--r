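test_that("fitness follows the weighted error/size trade-off exactly", {
  expect_equal(fitness(0, 10, 10, omega = 0.9), 0.1)
  expect_equal(fitness(1, 10, 10, omega = 0.9), 1.0)
  expect_equal(fitness(1, 7, 7, omega = 0.37), 1.0)
  expect_equal(fitness(0.1, 2, 200, omega = 0.99), 0.0991)
  expect_error(fitness(0.5, 1, 0))
  # strictly increasing in both error rate and subset size
  expect_gt(fitness(0.3, 5, 50), fitness(0.2, 5, 50))
  expect_gt(fitness(0.2, 9, 50), fitness(0.2, 5, 50))
})

test_that("perfectly separated clusters give zero CV error for any covering mask", {
  withr::local_seed(88)
  d <- separated_clusters(n_per_class = 10, q = 3)
  for (mask in list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))) {
    expect_equal(knn_cv_error(d, mask, fitness_config(seed = 4)), 0)
  }
})

test_that("stratified-CV error matches the exhaustive LOOCV oracle on tiny data", {
  withr::local_seed(909)
  for (rep in 1:50) {
    d <- random_tiny_dataset(n_max = 12, n_classes = sample(2:3, 1))
    k <- sample(1:5, 1)
    cfg <- fitness_config(knn_k = k, cv_folds = 5, seed = rep)
    got <- knn_cv_error(d, rep(1, d$q), cfg)  # tiny classes force LOOCV
    want <- loocv_knn_oracle(d$x, d$labels, k)
    expect_equal(got, want)
  }
})

test_that("a hand-enumerated 1-NN LOOCV error is reproduced", {
  # 1-d points 0,1,2, 10,11,12; classes a,a,a,b,b,b; every left-out point's
  # nearest neighbour shares its class -> error 0. Moving point 3 to the b
  # side (value 9.6) makes its nearest neighbour b while it stays labelled
  # a, and 10's nearest neighbour becomes the mislabelled 9.6 -> 2/6.
  d0 <- labeled_dataset(cbind(v = c(0, 1, 2, 10, 11, 12)),
                        rep(c("a", "b"), each = 3))
  cfg <- fitness_config(knn_k = 1, cv_folds = 5, seed = 1)
  expect_equal(knn_cv_error(d0, 1, cfg), 0)

  d1 <- labeled_dataset(cbind(v = c(0, 1, 9.6, 10, 11, 12)),
                        rep(c("a", "b"), each = 3))
  expect_equal(knn_cv_error(d1, 1, cfg), 2 / 6)
})

test_that("labels shuffled against features give chance-level error", {
  withr::local_seed(55)
  errs <- replicate(50, {
    d <- labeled_dataset(cbind(noise = rnorm(20)), sample(rep(c("a", "b"), 10)))
    knn_cv_error(d, 1, fitness_config(seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("fold assignment is seed-stable and order-invariant", {
  withr::local_seed(21)
  x <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(c("a", "b", "c"), 10)
  d <- labeled_dataset(x, labels)
  cfg <- fitness_config(seed = 17)
  e1 <- knn_cv_error(d, c(1, 1, 0, 1), cfg)
  e2 <- knn_cv_error(d, c(1, 1, 0, 1), cfg)
  expect_identical(e1, e2)

  perm <- sample(30)
  dp <- labeled_dataset(x[perm, ], labels[perm], sample_ids = d$sample_ids[perm])
  expect_equal(knn_cv_error(dp, c(1, 1, 0, 1), cfg), e1)
})

test_that("antibody evaluation caches by mask and obeys the size penalty", {
  withr::local_seed(2)
  d <- labeled_dataset(matrix(rnorm(20 * 6), 20, 6), rep(c("a", "b"), 10))
  cache <- hfia:::new_fitness_cache()
  cfg <- fitness_config(seed = 5)
  r1 <- hfia:::evaluate_antibody(c(1L, 0L, 1L, 0L, 0L, 0L), d, cfg, cache)
  r2 <- hfia:::evaluate_antibody(c(1L, 0L, 1L, 0L, 0L, 0L), d, cfg, cache)
  expect_identical(r1, r2)
  expect_equal(cache$n_evals, 1L)  # second call hit the cache

  expect_equal(r1$fitness, fitness(r1$error_rate, 2, 6, cfg$omega))

  # all-ones mask: size term is exactly (1 - omega)
  r3 <- hfia:::evaluate_antibody(rep(1L, 6), d, cfg, cache)
  expect_equal(r3$fitness - cfg$omega * r3$error_rate, 1 - cfg$omega)

  # superset with equal error must score strictly worse
  expect_lt(fitness(0.2, 2, 6, cfg$omega), fitness(0.2, 5, 6, cfg$omega))
  expect_error(knn_cv_error(d, rep(0, 6), cfg), "no active features")
})

test_that("standardisation uses training-fold statistics and changes distances", {
  withr::local_seed(13)
  # feature 2 dominates raw distances through scale alone
  x <- cbind(sig = c(rnorm(10, 0, 0.3), rnorm(10, 2, 0.3)),
             big = rnorm(20, 0, 1000))
  d <- labeled_dataset(x, rep(c("a", "b"), each = 10))
  raw <- knn_cv_error(d, c(1, 1), fitness_config(seed = 3))
  std <- knn_cv_error(d, c(1, 1), fitness_config(seed = 3, standardize = TRUE))
  expect_gt(raw, std)
  expect_equal(std, 0)
})

test_that("our deterministic KNN agrees with class::knn on tie-free data", {
  skip_if_not_installed("class")
  withr::local_seed(77)
  tr <- matrix(rnorm(40 * 3), 40, 3)
  te <- matrix(rnorm(15 * 3), 15, 3)
  y <- factor(rep(c("a", "b"), 20))
  ours <- hfia:::knn_predict(tr, as.integer(y), te, k = 3, n_levels = 2)
  ref <- as.integer(class::knn(tr, te, y, k = 3))
  expect_equal(ours, ref)
})
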