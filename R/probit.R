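#' Probit transform and its inverse
#'
#' `probit(p)` maps a proportion to the standard-normal quantile scale on
#' which the hierarchical model operates; `inv_probit(z)` is the standard
#' normal CDF mapping back to proportions.
#'
#' @param p proportion strictly inside (0, 1).
#' @param z probit-scale value.
#' @return numeric vector.
#' @examples
#' probit(0.03)       # about -1.881
#' inv_probit(0)      # 0.5
#' @export
probit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)")
  qnorm(p)
}

#' @rdname probit
#' @export
inv_probit <- function(z) pnorm(z)

#' Prevalence range implied by a probit-scale prior on the mean
#'
#' Translates a normal prior on the probit-transformed population prevalence
#' into the range of prevalences considered probable within `k` prior
#' standard deviations. Used to calibrate (and communicate) the mildly
#' informative default prior.
#'
#' @param theta_mean prior mean on the probit scale.
#' @param theta_sd prior standard deviation on the probit scale (>= 0).
#' @param k number of standard deviations (default 2).
#' @return numeric vector `c(low, high)` of proportions.
#' @examples
#' prior_prevalence_range(-1.88, 0.30)  # roughly 0.7% to 10.0%
#' @export
prior_prevalence_range <- function(theta_mean, theta_sd, k = 2) {
  stopifnot(theta_sd >= 0, k >= 0)
  c(low = pnorm(theta_mean - k * theta_sd),
    high = pnorm(theta_mean + k * theta_sd))
}

#' Study-level prevalence range implied by between-study heterogeneity
#'
#' Given a mean prevalence and a probit-scale between-study standard
#' deviation `tau`, returns the range within which `k` standard deviations of
#' "true" study-specific prevalences fall.
#'
#' @param mean_prev mean prevalence, a proportion in (0, 1).
#' @param tau probit-scale between-study SD (>= 0).
#' @param k number of standard deviations (default 2).
#' @return numeric vector `c(low, high)` of proportions.
#' @examples
#' implied_study_range(0.03, 0.5)  # roughly 0.2% to 18.9%
#' @export
implied_study_range <- function(mean_prev, tau, k = 2) {
  stopifnot(tau >= 0, k >= 0)
  z <- probit(mean_prev)
  c(low = pnorm(z - k * tau), high = pnorm(z + k * tau))
}

#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing at least `mass` of the sorted
#' sample values.
#'
#' @param samples numeric vector of draws.
#' @param mass interval mass (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 1) stop("empty sample")
  if (n == 1) return(c(low = x, high = x))
  m <- ceiling(mass * n)              # number of samples the interval must hold
  if (m >= n) return(c(low = x[1], high = x[n]))
  w <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(w)
  c(low = x[i], high = x[i + m - 1])
}
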