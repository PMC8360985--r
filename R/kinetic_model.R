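## Closed-form machinery for first-order kinetics with a stochastic rate.
##
## The model: d[X]/dt = -s * (mu_k + sigma_k * eta(t)) [X], with s = +1 for a
## sink and -1 for a formation process, and eta(t) Gaussian white noise.  Under
## the Ito interpretation ln X(t) is Gaussian with
##   mean      mu(t)     = mu0 + (s_drift * mu_k - 0.5 sigma_k^2) t,
##   variance  sigma2(t) = sigma0^2 + sigma_k^2 t,
## where s_drift = -1 (sink) / +1 (formation).  For a sink this is the familiar
## mu(t) = mu0 - (mu_k + 0.5 sigma_k^2) t.  The Ito convention is forced by
## that drift correction; under Stratonovich the 0.5 sigma_k^2 term would be
## absent.

#' Stochastic rate specification
#'
#' Describes a first-order rate \eqn{k(t) = \mu_k + \sigma_k \eta(t)} with
#' constant deterministic part `mu_k` (units 1/time) and Gaussian white-noise
#' fluctuations of intensity `sigma_k` (units 1/sqrt(time), the diffusion
#' intensity multiplying a Wiener increment).  `direction` selects whether the
#' rate acts as a loss (`"sink"`) or a production (`"formation"`) term; it
#' flips the drift sign only.
#'
#' @param mu_k Mean rate, non-negative (strictly positive for [lifetime()]).
#' @param sigma_k Fluctuation magnitude, non-negative.
#' @param direction `"sink"` (default) or `"formation"`.
#' @return An object of class `rate_model`.
#' @examples
#' rate_model(mu_k = 1, sigma_k = 0.5)
#' @seealso [evolve_log_params()], [lifetime()]
#' @export
rate_model <- function(mu_k, sigma_k, direction = c("sink", "formation")) {
  direction <- match.arg(direction)
  check_number(mu_k, "mu_k", lower = 0)
  check_number(sigma_k, "sigma_k", lower = 0)
  structure(
    list(mu_k = as.numeric(mu_k), sigma_k = as.numeric(sigma_k),
         direction = direction),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s process: mu_k = %g [1/time], sigma_k = %g [1/sqrt(time)]\n",
              x$direction, x$mu_k, x$sigma_k))
  invisible(x)
}

## sign of mu_k in the Ito log-drift: -1 sink, +1 formation
drift_sign <- function(rate) if (rate$direction == "sink") -1 else +1

## Ito drift of ln X
log_drift <- function(rate) drift_sign(rate) * rate$mu_k - 0.5 * rate$sigma_k^2

#' Gaussian white-noise specification
#'
#' The stochastic forcing is fixed to Gaussian white noise: independent
#' standard-normal increments scaled by `sqrt(dt)` in discrete schemes
#' (mean zero, unit variance per unit time).  The only free field is the
#' integer seed that makes every simulation reproducible.
#'
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(1L)
#' @export
noise_spec <- function(seed) {
  check_number(seed, "seed")
  if (abs(seed) >= .Machine$integer.max)
    stop("`seed` must be representable as a 32-bit integer", call. = FALSE)
  structure(list(kind = "gaussian-white", seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> Gaussian white noise, seed = %d\n", x$seed))
  invisible(x)
}

#' Log-space parameters of a log-normal distribution
#'
#' Location `mu` and variance `sigma2` of the logarithm of the concentration.
#' Parameters are stored as a log-space *variance* (not a standard deviation)
#' because the time-evolution laws are linear in the variance; [log_sd()]
#' exposes the standard deviation.
#'
#' @param mu Log-space location (log concentration, dimensionless).
#' @param sigma2 Log-space variance, `>= 0`.  `sigma2 = 0` describes a point
#'   mass (allowed as an initial condition; rejected by [lognormal_pdf()]).
#' @return An object of class `lognormal_params`.
#' @examples
#' p <- lognormal_params(mu = 0, sigma2 = 0.04)
#' lognormal_mean(p)
#' @export
lognormal_params <- function(mu, sigma2) {
  check_number(mu, "mu")
  check_number(sigma2, "sigma2", lower = 0)
  structure(list(mu = as.numeric(mu), sigma2 = as.numeric(sigma2)),
            class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("<lognormal_params> mu = %g, sigma2 = %g (mean = %g)\n",
              x$mu, x$sigma2, lognormal_mean(x)))
  invisible(x)
}

#' @rdname lognormal_params
#' @param params A `lognormal_params` object.
#' @export
log_sd <- function(params) {
  stopifnot(inherits(params, "lognormal_params"))
  sqrt(params$sigma2)
}

#' @rdname lognormal_params
#' @details `lognormal_mean()` returns the arithmetic mean
#'   \eqn{\exp(\mu + \sigma^2/2)}.
#' @export
lognormal_mean <- function(params) {
  stopifnot(inherits(params, "lognormal_params"))
  exp(params$mu + 0.5 * params$sigma2)
}

#' Deterministic first-order decay
#'
#' Solution of d\[X\]/dt = -k \[X\] with constant rate: `x0 * exp(-k * t)`.
#'
#' @param x0 Initial concentration, `> 0`.
#' @param k Decay rate, `>= 0`.
#' @param t Time (scalar or vector), `>= 0`.
#' @return Concentration(s) at time `t`.
#' @examples
#' deterministic_decay(1, k = 1, t = 1)  # exp(-1)
#' @export
deterministic_decay <- function(x0, k, t) {
  check_number(x0, "x0", lower = 0, strict = TRUE)
  check_number(k, "k", lower = 0)
  check_numeric_vec(t, "t", lower = 0)
  x0 * exp(-k * t)
}

#' Log-normal probability density
#'
#' Density of a log-normal distribution with log-space parameters
#' \eqn{(\mu, \sigma^2)}:
#' \deqn{P(x) = \frac{1}{x\sqrt{2\pi\sigma^2}}
#'   \exp\left(-\frac{(\ln x - \mu)^2}{2\sigma^2}\right).}
#'
#' @param x Concentration(s), strictly positive (the density lives on
#'   positive support only).
#' @param params [lognormal_params()] with `sigma2 > 0`.
#' @return Density value(s).
#' @examples
#' lognormal_pdf(1, lognormal_params(0, 1))  # 1/sqrt(2*pi)
#' @export
lognormal_pdf <- function(x, params) {
  stopifnot(inherits(params, "lognormal_params"))
  if (params$sigma2 <= 0)
    stop("degenerate distribution: sigma2 must be > 0 for a density",
         call. = FALSE)
  check_numeric_vec(x, "x", lower = 0, strict = TRUE)
  stats::dlnorm(x, meanlog = params$mu, sdlog = sqrt(params$sigma2))
}

#' Time evolution of the log-space parameters
#'
#' Under a stochastic first-order rate the concentration stays log-normal with
#' \deqn{\mu(t) = \mu_0 + (s\,\mu_k - \sigma_k^2/2)\,t, \qquad
#'       \sigma^2(t) = \sigma_0^2 + \sigma_k^2\,t,}
#' where \eqn{s = -1} for a sink and \eqn{+1} for a formation process (Ito
#' convention; for a sink the location drift is the familiar
#' \eqn{-(\mu_k + \sigma_k^2/2)}).  The variance growth is
#' direction-independent.
#'
#' @param initial [lognormal_params()] at `t = 0`.
#' @param rate [rate_model()].
#' @param t Time, `>= 0` (scalar).
#' @return [lognormal_params()] at time `t`.
#' @examples
#' evolve_log_params(lognormal_params(0, 0), rate_model(1, 0.5), t = 1)
#' @export
evolve_log_params <- function(initial, rate, t) {
  stopifnot(inherits(initial, "lognormal_params"), inherits(rate, "rate_model"))
  check_number(t, "t", lower = 0)
  lognormal_params(
    mu = initial$mu + log_drift(rate) * t,
    sigma2 = initial$sigma2 + rate$sigma_k^2 * t
  )
}

#' Mean concentration over time
#'
#' Arithmetic mean \eqn{\exp(\mu(t) + \sigma^2(t)/2)} of the evolving
#' log-normal.  For a sink this equals the ordinary exponential decay of the
#' initial mean, \eqn{X(0) e^{-\mu_k t}} with
#' \eqn{X(0) = \exp(\mu_0 + \sigma_0^2/2)}: the stochastic part cancels from
#' the mean because the noise has zero mean (algebraic identity).  For a
#' formation process the mean grows as \eqn{X(0) e^{+\mu_k t}}.
#'
#' @inheritParams evolve_log_params
#' @param t Time(s), `>= 0` (vectorized).
#' @return Mean concentration(s) at `t`.
#' @examples
#' mean_concentration(lognormal_params(0, 0), rate_model(1, 0.7), t = 2)  # exp(-2)
#' @export
mean_concentration <- function(initial, rate, t) {
  stopifnot(inherits(initial, "lognormal_params"), inherits(rate, "rate_model"))
  check_numeric_vec(t, "t", lower = 0)
  ## exp(mu(t) + sigma2(t)/2) simplified: the sigma_k^2 terms cancel
  lognormal_mean(initial) * exp(drift_sign(rate) * rate$mu_k * t)
}

#' Kinetic lifetime
#'
#' Characteristic timescale \eqn{\tau = 1/\mu_k} of the mean first-order rate.
#' Log-normal concentration data at a receptor site suggest sink kinetics, so
#' a recovered `mu_k` (see [recover_kinetics()]) translates directly into a
#' lifetime estimate.
#'
#' @param rate [rate_model()] with `mu_k > 0`.
#' @return Lifetime, units of time.
#' @examples
#' lifetime(rate_model(0.5, 0.1))  # 2
#' @export
lifetime <- function(rate) {
  stopifnot(inherits(rate, "rate_model"))
  if (rate$mu_k <= 0)
    stop("no finite lifetime: mu_k must be > 0", call. = FALSE)
  1 / rate$mu_k
}
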