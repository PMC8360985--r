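## Diagnostics: log-normal fitting, log-normality testing, kinetic-parameter
## recovery from time-resolved ensembles, and closed-form propagation of
## log-normality through ratios and products (isotope signatures, rates,
## fluxes).

assert_positive_samples <- function(samples, context) {
  if (!is.numeric(samples) || length(samples) < 1L || anyNA(samples))
    stop(sprintf("%s requires a non-empty numeric vector without NA", context),
         call. = FALSE)
  bad <- which(samples <= 0)
  if (length(bad))
    stop(sprintf(paste0("%s requires strictly positive samples (the log ",
                        "transform is undefined otherwise); non-positive ",
                        "values at indices: %s%s. Non-detects/censored values ",
                        "are not handled -- remove or model them explicitly."),
                 context, paste(utils::head(bad, 10L), collapse = ", "),
                 if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L)
                 else ""),
         call. = FALSE)
  invisible(samples)
}

#' Maximum-likelihood log-normal fit
#'
#' Fits log-space parameters by maximum likelihood on the log scale:
#' `mu_hat` is the mean of the logs and `sigma2_ml` the ML variance
#' (divisor `n`); the unbiased variant (divisor `n - 1`) is reported
#' alongside.  Standard errors are `sqrt(sigma2/n)` for `mu_hat` and
#' `sigma2 * sqrt(2/n)` for the variance.  Non-positive samples are an error
#' listing the offending indices -- never silently dropped.
#'
#' @param samples Strictly positive numeric vector, `n >= 3`.
#' @return An object of class `lognormal_fit`: `mu_hat`, `sigma2_ml`,
#'   `sigma2_unbiased`, `se_mu`, `se_sigma2`, `n`, `loglik`, `degenerate`.
#' @examples
#' fit_lognormal(rlnorm(100, 1, 0.5))
#' @export
fit_lognormal <- function(samples) {
  assert_positive_samples(samples, "fit_lognormal()")
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  lx <- log(samples)
  mu_hat <- mean(lx)
  sigma2_ml <- sum((lx - mu_hat)^2) / n
  degenerate <- sigma2_ml == 0
  loglik <- if (degenerate) Inf else
    sum(stats::dlnorm(samples, mu_hat, sqrt(sigma2_ml), log = TRUE))
  structure(
    list(mu_hat = mu_hat,
         sigma2_ml = sigma2_ml,
         sigma2_unbiased = sigma2_ml * n / (n - 1),
         se_mu = sqrt(sigma2_ml / n),
         se_sigma2 = sigma2_ml * sqrt(2 / n),
         n = n, loglik = loglik, degenerate = degenerate),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> n = %d: mu_hat = %.4f (SE %.4f), sigma2_ml = %.4f (SE %.4f)%s\n",
              x$n, x$mu_hat, x$se_mu, x$sigma2_ml, x$se_sigma2,
              if (x$degenerate) " [degenerate: zero log-variance]" else ""))
  invisible(x)
}

#' @rdname fit_lognormal
#' @param fit A `lognormal_fit`.
#' @param unbiased Use the unbiased variance (default `FALSE`, i.e. ML).
#' @details `as_lognormal_params()` converts a fit back to
#'   [lognormal_params()].
#' @export
as_lognormal_params <- function(fit, unbiased = FALSE) {
  stopifnot(inherits(fit, "lognormal_fit"))
  lognormal_params(fit$mu_hat,
                   if (unbiased) fit$sigma2_unbiased else fit$sigma2_ml)
}

#' Test a sample for log-normality
#'
#' Log-transforms the data and applies a well-established normality test:
#' Shapiro-Wilk by default, Anderson-Darling as an alternative.  With
#' `transform = "none"` the test is applied to the raw values (a plain
#' normality test, used e.g. for the well-mixed convolution limit).  Samples
#' larger than `max_n` are subsampled with a fixed seed (reported in the
#' result) because the Shapiro-Wilk statistic is defined for `n <= 5000`.
#'
#' @param samples Numeric vector (strictly positive when
#'   `transform = "log"`), `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @param transform `"log"` (default) or `"none"`.
#' @param method `"shapiro"` (default) or `"anderson-darling"`.
#' @param max_n Subsampling cap (default 5000, the Shapiro-Wilk limit).
#' @param subsample_seed Seed for the cap subsample (default 1).
#' @return An object of class `normality_test`: `statistic`, `p_value`,
#'   `alpha`, `decision` (`"reject"` iff `p_value < alpha`), `transform`,
#'   `method`, `n`, `n_used`, `subsampled`.
#' @examples
#' test_lognormality(rlnorm(200), alpha = 0.05)
#' @export
test_lognormality <- function(samples, alpha = 0.05,
                              transform = c("log", "none"),
                              method = c("shapiro", "anderson-darling"),
                              max_n = 5000, subsample_seed = 1L) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  check_number(alpha, "alpha", lower = 0, strict = TRUE)
  if (alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  x <- if (transform == "log") {
    assert_positive_samples(samples, "test_lognormality()")
    log(samples)
  } else {
    check_numeric_vec(samples, "samples")
    samples
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  subsampled <- n > max_n
  if (subsampled)
    x <- withr::with_seed(as.integer(subsample_seed),
                          sample(x, max_n))
  ht <- switch(method,
    "shapiro" = stats::shapiro.test(x),
    "anderson-darling" = nortest::ad.test(x)
  )
  p <- unname(ht$p.value)
  structure(
    list(statistic = unname(ht$statistic), p_value = p, alpha = alpha,
         decision = if (p < alpha) "reject" else "not-reject",
         transform = transform, method = method,
         n = n, n_used = length(x), subsampled = subsampled),
    class = "normality_test"
  )
}

#' @export
print.normality_test <- function(x, ...) {
  cat(sprintf("<normality_test> %s on %s data: W/A = %.4f, p = %.4g -> %s at alpha = %g (n used = %d%s)\n",
              x$method, if (x$transform == "log") "log-transformed" else "raw",
              x$statistic, x$p_value, x$decision, x$alpha, x$n_used,
              if (x$subsampled) sprintf(", subsampled from %d", x$n) else ""))
  invisible(x)
}

#' Recover kinetic parameters from a time-resolved ensemble
#'
#' Inverts the parameter-evolution laws by ordinary least squares on the
#' per-time log-moments: the slope of the log-variance versus time estimates
#' `sigma_k^2` (clipped at zero with a flag when negative), and the slope of
#' the log-mean gives `mu_k` after removing the Ito drift correction:
#' `mu_k_hat = s * (b_mean + sigma_k2_hat / 2)` with `s = -1` for a sink and
#' `+1` for a formation ensemble.  Confidence intervals are percentile
#' bootstrap over paths.
#'
#' @param ensemble An `ensemble_trajectories` from [simulate_exact()],
#'   [simulate_euler_maruyama()] or [simulate_formation()] (or assembled from
#'   [read_concentration_table()]); needs `>= 3` time points and `>= 10`
#'   paths.
#' @param n_boot Bootstrap resamples (default 500; 0 disables the CIs).
#' @param boot_seed Seed for the bootstrap (default 1).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `kinetic_recovery`: `mu_k_hat`,
#'   `sigma_k2_hat`, `sigma_k2_clipped`, `slope_mean`, `slope_var`, `ci`
#'   (2 x 2 matrix, or `NULL`), `n_paths`, `n_times`, `direction`.
#' @examples
#' ens <- simulate_exact(1, rate_model(1, 0.5), simulation_grid(2, 10),
#'                       n_paths = 500, noise = noise_spec(1))
#' recover_kinetics(ens, n_boot = 50)
#' @export
recover_kinetics <- function(ensemble, n_boot = 500, boot_seed = 1L,
                             conf = 0.95) {
  stopifnot(inherits(ensemble, "ensemble_trajectories"))
  n_boot <- check_count(n_boot, "n_boot", lower = 0L)
  times <- ensemble$times
  lp <- log(ensemble$paths)
  if (length(times) < 3L)
    stop("need >= 3 time points: the two slopes are unidentifiable",
         call. = FALSE)
  if (nrow(lp) < 10L)
    stop("need >= 10 paths", call. = FALSE)
  s <- drift_sign(ensemble$rate)

  estimate <- function(mat) {
    m <- colMeans(mat)
    v <- apply(mat, 2L, stats::var)
    b_m <- stats::cov(times, m) / stats::var(times)
    b_v <- stats::cov(times, v) / stats::var(times)
    sigma_k2 <- max(b_v, 0)
    c(mu_k = s * (b_m + 0.5 * sigma_k2), sigma_k2 = sigma_k2,
      b_m = b_m, b_v = b_v)
  }
  est <- estimate(lp)

  ci <- NULL
  if (n_boot > 0L) {
    boots <- withr::with_seed(as.integer(boot_seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(lp), replace = TRUE)
        estimate(lp[idx, , drop = FALSE])[1:2]
      }, numeric(2))
    })
    a <- (1 - conf) / 2
    ci <- t(apply(boots, 1L, stats::quantile, probs = c(a, 1 - a)))
    rownames(ci) <- c("mu_k", "sigma_k2")
  }

  structure(
    list(mu_k_hat = unname(est["mu_k"]),
         sigma_k2_hat = unname(est["sigma_k2"]),
         sigma_k2_clipped = est["b_v"] < 0,
         slope_mean = unname(est["b_m"]),
         slope_var = unname(est["b_v"]),
         ci = ci, conf = conf,
         n_paths = nrow(lp), n_times = length(times),
         direction = ensemble$rate$direction),
    class = "kinetic_recovery"
  )
}

#' @export
print.kinetic_recovery <- function(x, ...) {
  cat(sprintf("<kinetic_recovery> %s ensemble (%d paths, %d times):\n",
              x$direction, x$n_paths, x$n_times))
  cat(sprintf("  mu_k_hat     = %.5f\n", x$mu_k_hat))
  cat(sprintf("  sigma_k2_hat = %.5f%s\n", x$sigma_k2_hat,
              if (x$sigma_k2_clipped) " [clipped at 0]" else ""))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CIs: mu_k [%.4f, %.4f], sigma_k2 [%.4f, %.4f]\n",
                100 * x$conf, x$ci[1, 1], x$ci[1, 2], x$ci[2, 1], x$ci[2, 2]))
  }
  invisible(x)
}

#' Log-normal parameters of a ratio of independent log-normals
#'
#' If `a` and `b` are independent log-normal variables, `a/b` is log-normal
#' with location `mu_a - mu_b` and variance `sigma_a^2 + sigma_b^2`.  This is
#' the basis for propagating log-normality into diagnostic ratios such as
#' isotope signatures.  Independence is assumed, not checked.
#'
#' @param a,b [lognormal_params()] of numerator and denominator.
#' @return [lognormal_params()] of the ratio.
#' @examples
#' ratio_params(lognormal_params(1, 0.04), lognormal_params(0.5, 0.05))
#' @export
ratio_params <- function(a, b) {
  stopifnot(inherits(a, "lognormal_params"), inherits(b, "lognormal_params"))
  lognormal_params(a$mu - b$mu, a$sigma2 + b$sigma2)
}

#' Log-normal parameters of derived rates and fluxes
#'
#' Rates proportional to a log-normal concentration, and fluxes defined as
#' the product of a rate and a concentration, stay log-normal.  With a
#' positive constant `c` of proportionality the parameters shift to
#' `(mu + log c, sigma2)`; with an independent log-normal factor they add:
#' `(mu1 + mu2, sigma1^2 + sigma2^2)`.  Independence is assumed for the
#' product case.
#'
#' @param conc [lognormal_params()] of the concentration.
#' @param proportionality A single positive constant, or a
#'   [lognormal_params()] for an independent log-normal factor.
#' @return [lognormal_params()] of the derived rate or flux.
#' @examples
#' derived_rate_flux(lognormal_params(0, 0.1), 2)
#' derived_rate_flux(lognormal_params(0, 0.1), lognormal_params(1, 0.2))
#' @export
derived_rate_flux <- function(conc, proportionality) {
  stopifnot(inherits(conc, "lognormal_params"))
  if (inherits(proportionality, "lognormal_params")) {
    lognormal_params(conc$mu + proportionality$mu,
                     conc$sigma2 + proportionality$sigma2)
  } else {
    check_number(proportionality, "proportionality", lower = 0, strict = TRUE)
    lognormal_params(conc$mu + log(proportionality), conc$sigma2)
  }
}
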