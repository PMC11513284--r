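# Candidate caseload/dose distributions: left-truncated normal, exponential,
# weibull and gamma, fitted by maximum likelihood and compared by AIC.
# Exponential uses its closed-form MLE; gamma and weibull go through
# fitdistrplus::fitdist; the truncated normal is maximized directly on the
# renormalized likelihood (its left limit is data-supplied, not estimated,
# so it carries 2 free parameters like the other two-parameter families).

DIST_FAMILIES <- c("truncated_normal", "exponential", "weibull", "gamma")

new_fitted_distribution <- function(family, parameters, loglik = NA_real_,
                                    n_obs = NA_integer_) {
  k <- n_free_parameters(family)
  structure(
    list(family = family,
         parameters = parameters,
         loglik = loglik,
         aic = if (is.na(loglik)) NA_real_ else 2 * k - 2 * loglik,
         n_obs = n_obs),
    class = "fitted_distribution"
  )
}

n_free_parameters <- function(family) {
  # truncated normal: left limit is supplied, not free
  switch(family,
         truncated_normal = 2L, exponential = 1L,
         weibull = 2L, gamma = 2L,
         stop("unknown family '", family, "'", call. = FALSE))
}

#' Construct a distribution object from known parameters
#'
#' Builds a `fitted_distribution` directly from stated parameter values (for
#' example a published table of fitted laws), without data. Parameter names:
#' truncated normal `mean`, `sd`, `left`; exponential `rate`; weibull `shape`,
#' `scale`; gamma `shape`, `rate`.
#'
#' @param family one of `"truncated_normal"`, `"exponential"`, `"weibull"`,
#'   `"gamma"`.
#' @param parameters named numeric vector of family parameters.
#' @return A `fitted_distribution` with `NA` log-likelihood.
#' @examples
#' dist_spec("truncated_normal", c(mean = 5.77, sd = 18.48, left = 1))
#' @export
dist_spec <- function(family, parameters) {
  family <- match.arg(family, DIST_FAMILIES)
  required <- switch(family,
                     truncated_normal = c("mean", "sd", "left"),
                     exponential = "rate",
                     weibull = c("shape", "scale"),
                     gamma = c("shape", "rate"))
  if (!all(required %in% names(parameters))) {
    stop("family '", family, "' needs parameters: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  positive <- setdiff(required, c("mean", "left"))
  if (any(parameters[positive] <= 0)) {
    stop("scale/rate/shape parameters must be strictly positive",
         call. = FALSE)
  }
  new_fitted_distribution(family, parameters[required])
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(sprintf("<fitted_distribution> %s(%s)\n", x$family,
              paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                    collapse = ", ")))
  if (!is.na(x$loglik)) {
    cat(sprintf("  loglik = %.3f, AIC = %.3f, n = %d\n",
                x$loglik, x$aic, x$n_obs))
  }
  invisible(x)
}

#' Fit one candidate family by maximum likelihood
#'
#' @param sample numeric vector of observations (n >= 10, strictly positive
#'   for the exponential/weibull/gamma families, all `>= left_limit` for the
#'   truncated normal).
#' @param family one of the four candidate families.
#' @param left_limit left truncation limit for the truncated normal; defaults
#'   to `min(sample)` when omitted. Ignored by the other families.
#' @return A `fitted_distribution` with MLE parameters, log-likelihood and
#'   AIC (`2k - 2 loglik` with `k` free parameters; the truncated normal's
#'   left limit is data-supplied and not counted).
#' @examples
#' x <- rgamma(200, shape = 12.8, rate = 0.92)
#' fit_family(x, "gamma")
#' @export
fit_family <- function(sample, family, left_limit = NULL) {
  family <- match.arg(family, DIST_FAMILIES)
  x <- as.numeric(sample)
  if (length(x) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (anyNA(x)) stop("sample contains NA", call. = FALSE)

  if (family == "truncated_normal") {
    if (is.null(left_limit)) left_limit <- min(x)
    if (any(x < left_limit)) {
      stop("observations below the left limit ", left_limit, call. = FALSE)
    }
    fit_tnorm(x, left_limit)
  } else if (family == "exponential") {
    if (any(x <= 0)) stop("exponential requires positive data", call. = FALSE)
    rate <- 1 / mean(x)
    ll <- sum(stats::dexp(x, rate, log = TRUE))
    new_fitted_distribution("exponential", c(rate = rate), ll, length(x))
  } else {
    if (any(x <= 0)) stop(family, " requires positive data", call. = FALSE)
    fd <- fitdistrplus::fitdist(x, switch(family, weibull = "weibull",
                                          gamma = "gamma"))
    if (anyNA(fd$estimate)) {
      stop("MLE for family '", family, "' did not converge", call. = FALSE)
    }
    new_fitted_distribution(family, fd$estimate, fd$loglik, length(x))
  }
}

# direct maximization of the left-truncated normal likelihood,
# moment-based start, sd on the log scale to keep it positive
fit_tnorm <- function(x, left) {
  nll <- function(theta) {
    -sum(dtnorm(x, theta[1], exp(theta[2]), left = left, log = TRUE))
  }
  start <- c(mean(x), log(max(stats::sd(x), 1e-6)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("truncated-normal MLE did not converge (optim code ",
         opt$convergence, ")", call. = FALSE)
  }
  est <- c(mean = opt$par[1], sd = exp(opt$par[2]), left = left)
  new_fitted_distribution("truncated_normal", est, -opt$value, length(x))
}

#' Fit several families and select by AIC
#'
#' Fits every candidate family to the sample and returns the fit minimizing
#' the Akaike Information Criterion. Families that fail to fit are dropped
#' (at least two must succeed). Exact AIC ties are broken by the order of
#' `candidates` and flagged.
#'
#' @inheritParams fit_family
#' @param candidates character vector of families to try.
#' @return The winning `fitted_distribution`, with attributes `"all_fits"`
#'   (list of every successful fit), `"aic_table"` (family, aic) and
#'   `"tie"` (logical).
#' @export
select_by_aic <- function(sample, candidates = DIST_FAMILIES,
                          left_limit = NULL) {
  fits <- list()
  for (fam in candidates) {
    f <- tryCatch(fit_family(sample, fam, left_limit = left_limit),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) < 2L) {
    stop("fewer than two candidate families fitted successfully",
         call. = FALSE)
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- which.min(aics)
  winner <- fits[[best]]
  attr(winner, "all_fits") <- fits
  attr(winner, "aic_table") <- data.frame(family = names(aics),
                                          aic = unname(aics))
  attr(winner, "tie") <- sum(abs(aics - aics[best]) < 1e-9) > 1L
  winner
}

#' Expected value of a fitted distribution
#'
#' @param dist a `fitted_distribution`.
#' @return The distribution's mean (for the truncated normal, the mean of the
#'   truncated law, which exceeds its location parameter).
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "fitted_distribution"))
  p <- dist$parameters
  switch(dist$family,
         truncated_normal = tnorm_mean(p[["mean"]], p[["sd"]], p[["left"]]),
         exponential = 1 / p[["rate"]],
         weibull = p[["scale"]] * gamma(1 + 1 / p[["shape"]]),
         gamma = p[["shape"]] / p[["rate"]])
}

#' Translate a distribution so its sampled mean hits a target
#'
#' Adjusts the location/scale of a fitted law so the expected value of draws
#' equals `target_sampled_mean`: the truncated normal shifts its location
#' (solved numerically, because the location parameter is not the mean of the
#' truncated law), gamma and weibull rescale, exponential adjusts its rate.
#'
#' @param dist a `fitted_distribution`.
#' @param target_sampled_mean desired expected value of sampled draws.
#' @return The translated `fitted_distribution` (log-likelihood dropped: the
#'   translated law no longer describes the fitting sample).
#' @examples
#' d <- dist_spec("truncated_normal", c(mean = 5.77, sd = 18.48, left = 1))
#' translated <- translate_to_mean(d, 23.78)
#' dist_mean(translated)  # 23.78
#' @export
translate_to_mean <- function(dist, target_sampled_mean) {
  stopifnot(inherits(dist, "fitted_distribution"))
  m <- target_sampled_mean
  p <- dist$parameters
  if (dist$family == "truncated_normal") {
    if (m <= p[["left"]]) {
      stop("target mean ", m, " is not attainable: it must exceed the left ",
           "limit ", p[["left"]], call. = FALSE)
    }
    f <- function(loc) tnorm_mean(loc, p[["sd"]], p[["left"]]) - m
    # tnorm mean is increasing in location and tends to `left` as loc -> -Inf
    lo <- m - 10 * p[["sd"]]
    while (f(lo) > 0) lo <- lo - 10 * p[["sd"]]
    sol <- stats::uniroot(f, c(lo, m), tol = 1e-12)
    p[["mean"]] <- sol$root
  } else if (dist$family == "exponential") {
    if (m <= 0) stop("target mean must be positive", call. = FALSE)
    p[["rate"]] <- 1 / m
  } else {
    if (m <= 0) stop("target mean must be positive", call. = FALSE)
    if (dist$family == "gamma") {
      p[["rate"]] <- p[["shape"]] / m
    } else {
      p[["scale"]] <- m / gamma(1 + 1 / p[["shape"]])
    }
  }
  new_fitted_distribution(dist$family, p, NA_real_, dist$n_obs)
}

#' Draw from a fitted distribution
#'
#' @param dist a `fitted_distribution`.
#' @param count number of draws (>= 1).
#' @param seed optional integer; when given, the draw is seeded and the
#'   global RNG state is restored afterwards.
#' @return Numeric vector of `count` draws. Truncated families never emit
#'   values below their left limit.
#' @export
sample_dist <- function(dist, count, seed = NULL) {
  stopifnot(inherits(dist, "fitted_distribution"), count >= 1)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  p <- dist$parameters
  switch(dist$family,
         truncated_normal = rtnorm(count, p[["mean"]], p[["sd"]], p[["left"]]),
         exponential = stats::rexp(count, p[["rate"]]),
         weibull = stats::rweibull(count, p[["shape"]], p[["scale"]]),
         gamma = stats::rgamma(count, p[["shape"]], p[["rate"]]))
}
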