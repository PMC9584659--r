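#' Standard Cauchy draws
#'
#' I.i.d. samples from the standard Cauchy distribution (location 0,
#' scale 1), the heavy-tailed generator behind population initialisation
#' and mutation-locus selection. Heavier tails than the Gaussian give the
#' search larger jumps and better escape from local optima.
#'
#' @param count Number of draws (>= 0).
#' @return Numeric vector of `count` draws from the global RNG stream.
#' @export
sample_standard_cauchy <- function(count) {
  stopifnot(count >= 0)
  rcauchy(count)
}

#' Cauchy cumulative distribution function
#'
#' `F(x; x0, gamma) = (1/pi) * arctan((x - x0) / gamma) + 0.5`. The
#' probability that a Cauchy draw falls below `x`; `1 - cauchy_cdf(t)` is
#' therefore the expected activation density when loci are switched on by
#' draws exceeding a threshold `t`.
#'
#' @param x Evaluation point(s).
#' @param x0 Location parameter (default 0).
#' @param gamma Scale parameter, > 0 (default 1).
#' @return Value(s) in (0, 1).
#' @examples
#' cauchy_cdf(0)       # 0.5 at the location
#' cauchy_cdf(1)       # 0.75
#' 1 - cauchy_cdf(-0.2)  # default gene-activation density at eta = -0.2
#' @export
cauchy_cdf <- function(x, x0 = 0, gamma = 1) {
  stopifnot(gamma > 0)
  atan((x - x0) / gamma) / pi + 0.5
}
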