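# Stochastic building blocks. Every sampler is parameterized by its mean (and
# a dispersion knob) so that age-class factors can scale family means
# directly, and every sampler degenerates to a point mass at the mean when its
# dispersion is zero -- the "all variances zeroed" mode used by the
# hand-checkable engine oracle.

#' Triangular samples on \[0, 1\]
#'
#' Inverse-CDF sampler for the triangular distribution with support
#' `[lo, hi]` and the given mode; used for illness seriousness. With
#' `lo == hi` the draw is degenerate.
#'
#' @param n Number of draws.
#' @param mode Mode of the triangle.
#' @param lo,hi Support bounds.
#' @return Numeric vector of draws.
#' @export
rtriangular <- function(n, mode = 0.3, lo = 0, hi = 1) {
  if (hi < lo || mode < lo || mode > hi) {
    rlang::abort("triangular parameters must satisfy lo <= mode <= hi")
  }
  if (hi - lo < .time_eps) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
    lo + sqrt(u * (hi - lo) * (mode - lo)),
    hi - sqrt((1 - u) * (hi - lo) * (hi - mode))
  )
}

#' Triangular distribution function
#'
#' @param q Quantiles.
#' @inheritParams rtriangular
#' @return CDF values; the independent check used in distribution-conformance
#'   tests.
#' @export
ptriangular <- function(q, mode = 0.3, lo = 0, hi = 1) {
  p <- numeric(length(q))
  fc <- (mode - lo) / (hi - lo)
  below <- q <= mode
  p[below] <- pmax(0, (q[below] - lo))^2 / ((hi - lo) * (mode - lo))
  p[!below] <- 1 - pmax(0, (hi - q[!below]))^2 / ((hi - lo) * (hi - mode))
  pmin(1, pmax(0, p))
}

#' Log-normal samples by mean and coefficient of variation
#'
#' Used for illness durations and service times. `cv = 0` returns the mean.
#'
#' @param n Number of draws.
#' @param mean Target mean (> 0).
#' @param cv Coefficient of variation (>= 0).
#' @return Strictly positive draws with `E[X] = mean`, `sd[X] = cv * mean`.
#' @export
rlnorm_mean_cv <- function(n, mean, cv) {
  if (any(mean <= 0)) rlang::abort("log-normal mean must be positive")
  if (cv <= 0) return(rep_len(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Weibull samples by mean and shape
#'
#' Used for the willingness to wait. The scale is solved from
#' `mean = scale * gamma(1 + 1/shape)`; `shape = Inf` (or a `mean` of zero)
#' degenerates to the mean.
#'
#' @param n Number of draws.
#' @param mean Target mean (>= 0).
#' @param shape Weibull shape `k` (> 0), default dispersion knob.
#' @return Non-negative draws with `E[X] = mean`.
#' @export
rweibull_mean <- function(n, mean, shape) {
  if (any(mean < 0)) rlang::abort("Weibull mean must be non-negative")
  if (!is.finite(shape)) return(rep_len(mean, n))
  if (shape <= 0) rlang::abort("Weibull shape must be positive")
  scale <- mean / gamma(1 + 1 / shape)
  out <- stats::rweibull(n, shape = shape, scale = rep_len(scale, n))
  out[rep_len(mean, n) == 0] <- 0
  out
}

#' Truncated-normal punctuality offsets
#'
#' Appointment patients arrive with a normal offset (minutes) around the
#' scheduled time; the realized arrival is clamped into the session window by
#' the caller. `sd = 0` gives perfectly punctual patients.
#'
#' @param n Number of draws.
#' @param sd Standard deviation in minutes.
#' @return Offsets in days.
#' @export
rpunctuality <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  stats::rnorm(n, 0, sd) / 1440
}

#' Beta-positioned walk-in arrival fractions
#'
#' Walk-ins arrive at a beta-distributed fraction of the session's open
#' window. Degenerate mode returns the distribution mean.
#'
#' @param n Number of draws.
#' @param shape1,shape2 Beta shape parameters.
#' @param degenerate If `TRUE`, return the mean fraction.
#' @return Fractions in `[0, 1]`.
#' @export
rarrival_fraction <- function(n, shape1 = 2, shape2 = 2, degenerate = FALSE) {
  if (degenerate) return(rep(shape1 / (shape1 + shape2), n))
  stats::rbeta(n, shape1, shape2)
}

#' Exponential inter-onset gaps
#'
#' Acute illness onsets form a homogeneous Poisson process per patient with
#' rate `annual_rate / 365` per day. In degenerate mode the gap equals its
#' mean `365 / annual_rate`.
#'
#' @param n Number of draws.
#' @param annual_rate Expected illnesses per year (>= 0); a zero rate gives
#'   `Inf` gaps (the patient never falls ill).
#' @param degenerate If `TRUE`, return the mean gap.
#' @return Gaps in days.
#' @export
ronset_gap <- function(n, annual_rate, degenerate = FALSE) {
  rate <- rep_len(annual_rate, n) / 365
  out <- rep(Inf, n)
  pos <- rate > 0
  if (degenerate) {
    out[pos] <- 1 / rate[pos]
  } else if (any(pos)) {
    out[pos] <- stats::rexp(sum(pos), rate[pos])
  }
  out
}
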