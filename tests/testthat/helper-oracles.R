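# Independent brute-force oracles and small fixture builders.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive double-loop Fisher score: between-class over within-class
# dispersion with population variances, denominator floored at 1e-12.
fisher_oracle <- function(x, labels) {
  labels <- factor(as.character(labels), levels = sort(unique(as.character(labels))))
  sapply(seq_len(ncol(x)), function(i) {
    v <- x[, i]
    u <- mean(v)
    num <- 0
    den <- 0
    for (lev in levels(labels)) {
      vk <- v[labels == lev]
      nk <- length(vk)
      num <- num + nk * (mean(vk) - u)^2
      den <- den + nk * mean((vk - mean(vk))^2)
    }
    num / max(den, 1e-12)
  })
}

# Exhaustive leave-one-out KNN: per test point, sort all other points by
# Euclidean distance, majority vote among the k nearest, vote ties to the
# smallest class label. Returns the misclassification fraction.
loocv_knn_oracle <- function(x, labels, k) {
  labels <- factor(as.character(labels), levels = sort(unique(as.character(labels))))
  y <- as.integer(labels)
  n <- nrow(x)
  wrong <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dd <- sapply(others, function(j) sqrt(sum((x[i, ] - x[j, ])^2)))
    kk <- min(k, length(others))
    nb <- y[others[order(dd)][seq_len(kk)]]
    counts <- sapply(seq_len(nlevels(labels)), function(lv) sum(nb == lv))
    pred <- which(counts == max(counts))[1]
    if (pred != y[i]) wrong <- wrong + 1
  }
  wrong / n
}

# Random continuous dataset with class sizes small enough to force the
# leave-one-out fallback (every class < cv_folds members).
random_tiny_dataset <- function(n_max = 12, n_classes = 2) {
  sizes <- sample(2:4, n_classes, replace = TRUE)
  while (sum(sizes) > n_max) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  n <- sum(sizes)
  q <- sample(2:5, 1)
  labeled_dataset(matrix(runif(n * q), n, q),
                  rep(letters[seq_len(n_classes)], times = sizes))
}

# Two tight, far-separated Gaussian clusters; any mask covering the
# separating features classifies perfectly.
separated_clusters <- function(n_per_class = 10, q = 3, gap = 100) {
  x <- rbind(matrix(rnorm(n_per_class * q, 0, 0.1), n_per_class, q),
             matrix(rnorm(n_per_class * q, gap, 0.1), n_per_class, q))
  labeled_dataset(x, rep(c("a", "b"), each = n_per_class))
}

small_planted <- function(seed, n = 60, q = 400, informative = 8, shift = 3) {
  make_dataset(synthetic_spec(n_samples = n, n_features = q,
                              n_informative = informative, mean_shift = shift,
                              seed = seed))
}

# Deterministic surrogate fitness over 8-bit codes: weighted Hamming
# distance to a 3-gene target plus a small subset-size penalty.
surrogate_fitness_8 <- function() {
  target <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
  w <- (seq_len(8) / 8)^2
  w <- w / sum(w)
  function(code) {
    0.9 * sum(w * (code != target)) + 0.1 * sum(code) / 8
  }
}

# All 255 non-empty 8-bit masks, for exhaustive enumeration.
all_masks_8 <- function() {
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  grid[rowSums(grid) > 0, , drop = FALSE]
}
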