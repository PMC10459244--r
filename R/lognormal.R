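#' Lognormal parameters from arithmetic moments
#'
#' Converts an arithmetic mean and standard deviation to the log-scale
#' parameters (`meanlog`, `sdlog`) of the lognormal distribution with exactly
#' those moments: `meanlog = ln(mean^2 / sqrt(sd^2 + mean^2))`,
#' `sdlog = sqrt(ln(1 + sd^2 / mean^2))`.
#'
#' @param mean arithmetic mean (> 0).
#' @param sd arithmetic standard deviation (>= 0); `sd = 0` gives the
#'   degenerate distribution at `mean`.
#' @return a list with components `meanlog` and `sdlog`.
#' @seealso [lognormal_moments_from_params()] for the inverse map.
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(sd) || sd < 0) stop("sd must be nonnegative")
  cv2 <- (sd / mean)^2
  list(meanlog = log(mean^2 / sqrt(sd^2 + mean^2)),
       sdlog = sqrt(log1p(cv2)))
}

#' Arithmetic moments of a lognormal distribution
#'
#' @param meanlog,sdlog log-scale parameters (`sdlog >= 0`).
#' @return a list with components `mean` and `sd`.
#' @export
lognormal_moments_from_params <- function(meanlog, sdlog) {
  stopifnot(is.finite(meanlog), is.finite(sdlog), sdlog >= 0)
  m <- exp(meanlog + sdlog^2 / 2)
  list(mean = m, sd = m * sqrt(expm1(sdlog^2)))
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler for the normal distribution restricted to
#' `[lower, upper]`. With `sd = 0` the distribution is degenerate and the mean
#' (clipped to the bounds) is returned.
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal.
#' @param lower,upper truncation bounds (`lower < upper`; infinite bounds
#'   allowed).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`, all values in `[lower, upper]`.
#' @export
sample_truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf,
                                    seed = NULL) {
  if (lower == upper && sd == 0) return(rep(lower, n))
  if (lower >= upper) stop("lower must be strictly less than upper")
  if (sd < 0) stop("sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lower), upper)
}
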