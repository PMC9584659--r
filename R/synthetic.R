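#' Specification of a synthetic planted-feature dataset
#'
#' Describes a labelled high-dimensional dataset of the kind the method
#' targets: thousands of mostly uninformative features, tens of samples,
#' a handful of class-informative features whose means differ between
#' classes. Defaults give the study condition used throughout the
#' package's experiments: 100 samples, 2000 features, 10 informative,
#' 2 classes, mean shift 3 noise-SDs.
#'
#' @param n_samples Number of samples.
#' @param n_features Total feature count `q`.
#' @param n_informative Number of planted informative features
#'   (`<= n_features`).
#' @param n_classes Number of classes `c >= 2`.
#' @param mean_shift Between-class separation of informative features, in
#'   noise-SD units: a class-`k` sample (k = 0, ..., c-1) has mean
#'   `k * mean_shift` on each informative feature.
#' @param noise_sd Noise standard deviation (> 0), default 1.
#' @param class_balance Optional class proportions summing to 1; default
#'   balanced. Every class must get at least 2 samples.
#' @param seed Integer seed; same spec + seed gives an identical dataset.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100, n_features = 2000,
                           n_informative = 10, n_classes = 2,
                           mean_shift = 3, noise_sd = 1,
                           class_balance = NULL, seed = 1L) {
  stopifnot(n_informative <= n_features, n_classes >= 2, noise_sd > 0,
            n_samples >= 2 * n_classes)
  if (is.null(class_balance)) {
    class_balance <- rep(1 / n_classes, n_classes)
  }
  stopifnot(length(class_balance) == n_classes,
            abs(sum(class_balance) - 1) < 1e-8)
  counts <- floor(class_balance * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    top <- order(-(class_balance * n_samples - counts))[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  if (any(counts < 2)) abort("infeasible class balance: a class gets < 2 samples")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_classes = as.integer(n_classes),
                 mean_shift = mean_shift, noise_sd = noise_sd,
                 class_counts = as.integer(counts), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labelled dataset with planted features
#'
#' All features are i.i.d. Gaussian noise with SD `noise_sd`, except that
#' on a seeded random subset of `n_informative` columns, samples of class
#' `k` (k = 0, ..., c-1) are shifted to mean `k * mean_shift`. The
#' ground-truth informative column indices are returned alongside the
#' data so recovery can be measured directly.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [labeled_dataset()]) and
#'   `informative_indices` (sorted integer vector).
#' @examples
#' synth <- make_dataset(synthetic_spec(n_samples = 20, n_features = 50,
#'                                      n_informative = 3, seed = 1))
#' synth$informative_indices
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    labels <- rep(seq_len(spec$n_classes) - 1L, times = spec$class_counts)
    x <- matrix(stats::rnorm(spec$n_samples * spec$n_features,
                             sd = spec$noise_sd),
                spec$n_samples, spec$n_features)
    informative <- sort(sample.int(spec$n_features, spec$n_informative))
    if (spec$n_informative > 0) {
      x[, informative] <- x[, informative] + labels * spec$mean_shift
    }
    list(
      dataset = labeled_dataset(x, paste0("c", labels),
                                feature_names = paste0("f", seq_len(spec$n_features) - 1L)),
      informative_indices = informative
    )
  })
}
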