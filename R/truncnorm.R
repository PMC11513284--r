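# Left-truncated normal distribution: density, CDF, quantiles, random draws and
# moments for a normal(mean, sd) law restricted to [left, Inf) with the density
# renormalized over the truncated support. The location parameter `mean` is NOT
# the expected value of the truncated law.

#' Left-truncated normal distribution
#'
#' Density, distribution function, quantile function, random generation and
#' expected value for the normal distribution with location `mean` and scale
#' `sd`, left-truncated at `left` (support `[left, Inf)`).
#'
#' The truncated density is `dnorm(x, mean, sd) / (1 - pnorm(left, mean, sd))`
#' for `x >= left` and 0 below. Note that `mean` is the location parameter of
#' the parent normal, not the expectation of the truncated law; use
#' [tnorm_mean()] for the latter.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mean location parameter of the parent normal.
#' @param sd scale parameter of the parent normal (> 0).
#' @param left left truncation limit (`-Inf` recovers the untruncated normal).
#' @param log logical; return log-density.
#'
#' @return `dtnorm` the density, `ptnorm` the CDF, `qtnorm` quantiles,
#'   `rtnorm` draws, `tnorm_mean` and `tnorm_var` the first two moments of the
#'   truncated law.
#'
#' @examples
#' integrate(dtnorm, 1, Inf, mean = 5.77, sd = 18.48, left = 1)$value  # 1
#' tnorm_mean(5.77, 18.48, left = 1)
#' @name tnorm
NULL

#' @rdname tnorm
#' @export
dtnorm <- function(x, mean = 0, sd = 1, left = -Inf, log = FALSE) {
  stopifnot(sd > 0)
  tail_mass <- stats::pnorm(left, mean, sd, lower.tail = FALSE)
  ld <- stats::dnorm(x, mean, sd, log = TRUE) - log(tail_mass)
  ld[x < left] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname tnorm
#' @export
ptnorm <- function(q, mean = 0, sd = 1, left = -Inf) {
  stopifnot(sd > 0)
  tail_mass <- stats::pnorm(left, mean, sd, lower.tail = FALSE)
  p <- (stats::pnorm(q, mean, sd) - stats::pnorm(left, mean, sd)) / tail_mass
  pmin(pmax(p, 0), 1)
}

#' @rdname tnorm
#' @export
qtnorm <- function(p, mean = 0, sd = 1, left = -Inf) {
  stopifnot(sd > 0, all(p >= 0 & p <= 1))
  p_left <- stats::pnorm(left, mean, sd)
  stats::qnorm(p_left + p * (1 - p_left), mean, sd)
}

#' @rdname tnorm
#' @export
rtnorm <- function(n, mean = 0, sd = 1, left = -Inf) {
  # inverse-CDF sampling: exact, vectorized, no rejection loop
  qtnorm(stats::runif(n), mean = mean, sd = sd, left = left)
}

#' @rdname tnorm
#' @export
tnorm_mean <- function(mean = 0, sd = 1, left = -Inf) {
  if (!is.finite(left)) return(mean)
  alpha <- (left - mean) / sd
  # inverse Mills ratio phi(alpha) / (1 - Phi(alpha)), stable in the upper tail
  lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                  stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  mean + sd * lambda
}

#' @rdname tnorm
#' @export
tnorm_var <- function(mean = 0, sd = 1, left = -Inf) {
  if (!is.finite(left)) return(sd^2)
  alpha <- (left - mean) / sd
  lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                  stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  sd^2 * (1 + alpha * lambda - lambda^2)
}
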