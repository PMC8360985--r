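## Generators for the three classes of mechanism that shape environmental
## concentration distributions: pure kinetics (log-normal), source mixing in
## its two limits (separated sources -> multi-modal mixture; well-mixed
## sources -> convolution tending to normal), and oscillatory modulation by
## external variables (diurnal/seasonal cycles).

#' Mixture specification
#'
#' A list of log-normal components with sampling weights, describing a system
#' whose observations reflect one source at a time (the "separated" limit of
#' source mixing).  In time-series mode an optional Markov stay-probability
#' `persistence` produces temporally persistent source blocks.
#'
#' @param components List of [lognormal_params()] (length `>= 1`).
#' @param weights Component probabilities; default equal.  Must be
#'   non-negative and sum to 1 (within 1e-12).
#' @param persistence Optional stay probability in `[0, 1)` for Markov
#'   switching; on a switch the chain moves to one of the other components
#'   with probabilities proportional to their weights.
#' @return An object of class `mixture_spec`.
#' @examples
#' mixture_spec(list(lognormal_params(-2, 0.04), lognormal_params(0, 0.04),
#'                   lognormal_params(2, 0.04)))
#' @export
mixture_spec <- function(components, weights = NULL, persistence = NULL) {
  if (!is.list(components) || length(components) < 1L ||
      !all(vapply(components, inherits, TRUE, "lognormal_params")))
    stop("`components` must be a non-empty list of lognormal_params",
         call. = FALSE)
  k <- length(components)
  if (is.null(weights)) weights <- rep(1 / k, k)
  check_numeric_vec(weights, "weights", lower = 0)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-12)
    stop("`weights` must have one entry per component and sum to 1",
         call. = FALSE)
  if (!is.null(persistence)) {
    check_number(persistence, "persistence", lower = 0)
    if (persistence >= 1)
      stop("`persistence` must be in [0, 1)", call. = FALSE)
  }
  structure(list(components = components, weights = weights,
                 persistence = persistence),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %d log-normal components, weights = %s%s\n",
              length(x$components),
              paste(signif(x$weights, 3), collapse = ", "),
              if (is.null(x$persistence)) ""
              else sprintf(", persistence = %g", x$persistence)))
  invisible(x)
}

#' Oscillatory modulation specification
#'
#' Sinusoidal modulation of the log-concentration with dimensionless
#' log-space amplitude `amplitude`, period `period` (time units) and phase
#' `phase` (radians) -- a stylized diurnal or seasonal cycle acting on top of
#' the kinetic log-normal.
#'
#' @param amplitude `A >= 0` (log-space, dimensionless).
#' @param period `T > 0` (time).
#' @param phase Radians (default 0).
#' @return An object of class `oscillation_spec`.
#' @examples
#' oscillation_spec(amplitude = 2, period = 1)
#' @export
oscillation_spec <- function(amplitude, period, phase = 0) {
  check_number(amplitude, "amplitude", lower = 0)
  check_number(period, "period", lower = 0, strict = TRUE)
  check_number(phase, "phase")
  structure(list(amplitude = amplitude, period = period, phase = phase),
            class = "oscillation_spec")
}

#' Sample i.i.d. kinetic (log-normal) concentrations
#'
#' Draws `n` independent log-normal concentrations -- the stationary-shape
#' outcome of first-order kinetics with a stochastic rate at a fixed
#' observation time.
#'
#' @param params [lognormal_params()].
#' @param n Number of draws, `>= 1`.
#' @param noise [noise_spec()].
#' @return Numeric vector of `n` strictly positive samples.
#' @examples
#' x <- sample_kinetic(lognormal_params(0, 1), 1000, noise_spec(1))
#' @export
sample_kinetic <- function(params, n, noise) {
  stopifnot(inherits(params, "lognormal_params"), inherits(noise, "noise_spec"))
  n <- check_count(n, "n")
  withr::with_seed(noise$seed,
    stats::rlnorm(n, meanlog = params$mu, sdlog = sqrt(params$sigma2)))
}

#' Sample from a mixture of log-normal states
#'
#' Each observation reflects a single source/state: a component is chosen per
#' draw, either independently by the weights (`mode = "iid"`) or by a Markov
#' chain with stay probability `spec$persistence` (`mode = "markov"`,
#' time-series realism with persistent blocks).  The hidden state labels are
#' returned for testability.
#'
#' @param spec [mixture_spec()].
#' @param n Number of draws.
#' @param noise [noise_spec()].
#' @param mode `"iid"` (default) or `"markov"` (requires `persistence`).
#' @return A list with `samples` (positive numeric) and `states` (integer
#'   component labels).
#' @examples
#' sp <- mixture_spec(list(lognormal_params(-2, 0.04), lognormal_params(2, 0.04)))
#' out <- sample_mixture(sp, 1000, noise_spec(1))
#' table(out$states)
#' @export
sample_mixture <- function(spec, n, noise, mode = c("iid", "markov")) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(noise, "noise_spec"))
  mode <- match.arg(mode)
  n <- check_count(n, "n")
  k <- length(spec$components)
  if (mode == "markov" && is.null(spec$persistence))
    stop("markov mode requires `persistence` in the mixture_spec",
         call. = FALSE)

  withr::with_seed(noise$seed, {
    states <- if (mode == "iid" || k == 1L) {
      sample.int(k, n, replace = TRUE, prob = spec$weights)
    } else {
      s <- integer(n)
      s[1] <- sample.int(k, 1L, prob = spec$weights)
      for (i in seq_len(n - 1L)) {
        if (stats::runif(1) < spec$persistence) {
          s[i + 1L] <- s[i]
        } else {
          w <- spec$weights
          w[s[i]] <- 0
          s[i + 1L] <- if (sum(w) > 0) sample.int(k, 1L, prob = w)
                       else s[i]
        }
      }
      s
    }
    mus <- vapply(spec$components, `[[`, 0, "mu")
    sds <- sqrt(vapply(spec$components, `[[`, 0, "sigma2"))
    list(samples = stats::rlnorm(n, mus[states], sds[states]),
         states = states)
  })
}

#' Sample sums of independent sources (convolution)
#'
#' The well-mixed limit of source mixing: each observation is the sum of one
#' independent draw from *every* component (weights are ignored).  By the
#' Central Limit Theorem the sum of many comparable sources tends towards a
#' normal distribution on the raw concentration scale.  Repeated i.i.d.
#' sources are expressed by listing one component several times (see
#' [replicate_components()]).
#'
#' @param spec [mixture_spec()]; all components are summed per draw.
#' @param n Number of draws.
#' @param noise [noise_spec()].
#' @return Numeric vector of `n` positive samples.
#' @examples
#' sp <- mixture_spec(replicate_components(lognormal_params(0, 0.25), 30))
#' x <- sample_convolution(sp, 500, noise_spec(1))
#' @export
sample_convolution <- function(spec, n, noise) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(noise, "noise_spec"))
  n <- check_count(n, "n")
  k <- length(spec$components)
  mus <- vapply(spec$components, `[[`, 0, "mu")
  sds <- sqrt(vapply(spec$components, `[[`, 0, "sigma2"))
  withr::with_seed(noise$seed, {
    draws <- matrix(stats::rlnorm(n * k, rep(mus, each = n), rep(sds, each = n)),
                    nrow = n, ncol = k)
    rowSums(draws)
  })
}

#' @rdname sample_convolution
#' @param params A [lognormal_params()] to replicate.
#' @param k Number of i.i.d. copies.
#' @export
replicate_components <- function(params, k) {
  stopifnot(inherits(params, "lognormal_params"))
  k <- check_count(k, "k")
  rep(list(params), k)
}

#' Sample an oscillation-modulated log-normal
#'
#' Concentrations observed at times uniform over one period of an external
#' cycle, with the modulation additive in log space (multiplicative in
#' concentration, hence positivity-preserving):
#' \deqn{X = \exp(\mu + A \sin(2\pi t / T + \phi) + \sigma Z).}
#' Over uniform sampling times the modulation adds `A^2/2` to the
#' log-variance; for `A` large against `sigma` the log-marginal becomes
#' bimodal and log-normality is rejected.
#'
#' The Gaussian log-noise is drawn before the sampling times, so with
#' `amplitude = 0` the samples coincide bit-for-bit with
#' [sample_kinetic()] under the same seed.
#'
#' @param base [lognormal_params()] of the unmodulated kinetic distribution.
#' @param osc [oscillation_spec()].
#' @param n Number of draws.
#' @param noise [noise_spec()].
#' @return A list with `samples` (positive numeric) and `times` (uniform over
#'   one period).
#' @examples
#' out <- sample_oscillatory(lognormal_params(0, 0.04),
#'                           oscillation_spec(2, 1), 1000, noise_spec(1))
#' @export
sample_oscillatory <- function(base, osc, n, noise) {
  stopifnot(inherits(base, "lognormal_params"),
            inherits(osc, "oscillation_spec"), inherits(noise, "noise_spec"))
  n <- check_count(n, "n")
  withr::with_seed(noise$seed, {
    z <- stats::rnorm(n)   # drawn first: amplitude = 0 matches sample_kinetic
    tm <- stats::runif(n, 0, osc$period)
    lx <- base$mu + osc$amplitude * sin(2 * pi * tm / osc$period + osc$phase) +
      sqrt(base$sigma2) * z
    list(samples = exp(lx), times = tm)
  })
}

#' Count modes of a sample's kernel density
#'
#' Counts local maxima of a Gaussian kernel density estimate, by default on
#' the log scale (where log-normal mixture components have equal widths).  A
#' maximum counts as a mode only if it rises at least `min_prominence` of the
#' global peak height above the higher of its neighbouring minima, which
#' suppresses ripple modes.
#'
#' @param samples Positive numeric vector.
#' @param log Estimate the density of `log(samples)` (default `TRUE`).
#' @param min_prominence Required prominence as a fraction of the peak height
#'   (default 0.05).
#' @param ... Passed to [stats::density()].
#' @return Integer mode count.
#' @examples
#' sp <- mixture_spec(list(lognormal_params(-2, 0.04), lognormal_params(2, 0.04)))
#' count_density_modes(sample_mixture(sp, 5000, noise_spec(1))$samples)
#' @export
count_density_modes <- function(samples, log = TRUE, min_prominence = 0.05,
                                ...) {
  check_numeric_vec(samples, "samples", lower = 0, strict = TRUE)
  x <- if (log) base::log(samples) else samples
  d <- stats::density(x, ...)
  y <- d$y
  n <- length(y)
  ds <- diff(sign(diff(y)))
  maxima <- which(ds == -2) + 1L
  minima <- which(ds == 2) + 1L
  if (y[1] > y[2]) maxima <- c(1L, maxima)
  if (y[n] > y[n - 1L]) maxima <- c(maxima, n)
  peak <- max(y)
  count <- 0L
  for (m in maxima) {
    left <- minima[minima < m]
    right <- minima[minima > m]
    floor_left <- if (length(left)) y[max(left)] else 0
    floor_right <- if (length(right)) y[min(right)] else 0
    if (y[m] - max(floor_left, floor_right) >= min_prominence * peak)
      count <- count + 1L
  }
  count
}
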