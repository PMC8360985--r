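test_that("maximum-likelihood fit recovers log-space parameters", {
  n <- 1e5
  x <- withr::with_seed(1, exp(rnorm(n)))
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$mu_hat), se3(1, n))
  expect_lt(abs(fit$sigma2_ml - 1), 3 * sqrt(2 / n))
  expect_equal(fit$sigma2_unbiased, fit$sigma2_ml * n / (n - 1))
  expect_equal(fit$se_mu, sqrt(fit$sigma2_ml / n))
  # scaling all samples shifts mu by log(c) and leaves sigma2 unchanged
  fit2 <- fit_lognormal(3 * x)
  expect_equal(fit2$mu_hat, fit$mu_hat + log(3))
  expect_equal(fit2$sigma2_ml, fit$sigma2_ml)
})

test_that("constant samples yield a degenerate fit, non-positive ones an error", {
  fit <- fit_lognormal(rep(5, 10))
  expect_equal(fit$mu_hat, log(5))
  expect_equal(fit$sigma2_ml, 0)
  expect_true(fit$degenerate)
  err <- tryCatch(fit_lognormal(c(1, -2, 3, 0)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "indices")
  expect_match(err, "2, 4")
})

test_that("fit round-trips over random parameter draws", {
  set.seed(5)
  for (i in 1:20) {
    p <- lognormal_params(rnorm(1), runif(1, 0.05, 2))
    n <- 5000
    x <- sample_kinetic(p, n, noise_spec(500 + i))
    fit <- fit_lognormal(x)
    expect_lt(abs(fit$mu_hat - p$mu), se3(sqrt(p$sigma2), n))
    expect_lt(abs(fit$sigma2_ml - p$sigma2), 3 * p$sigma2 * sqrt(2 / n))
  }
})

test_that("log-normality testing equals normality testing of the logs", {
  x <- withr::with_seed(2, rlnorm(500, 1, 0.4))
  a <- test_lognormality(x)
  b <- test_lognormality(log(x), transform = "none")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
  expect_identical(a$decision == "reject", a$p_value < a$alpha)
  err <- tryCatch(test_lognormality(c(1, 0, 2)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "log")
})

test_that("the test rejects clearly non-log-normal data", {
  rejected <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, runif(1000, 1, 2))
    test_lognormality(x, alpha = 0.01)$decision == "reject"
  }, TRUE)
  expect_true(all(rejected))
})

test_that("large samples are subsampled reproducibly for Shapiro-Wilk", {
  x <- withr::with_seed(3, rlnorm(12000))
  a <- test_lognormality(x)
  b <- test_lognormality(x)
  expect_true(a$subsampled)
  expect_equal(a$n_used, 5000)
  expect_identical(a$p_value, b$p_value)
  # the Anderson-Darling alternative runs on the full sample
  ad <- test_lognormality(x, method = "anderson-darling", max_n = 2e4)
  expect_false(ad$subsampled)
})

test_that("noiseless analytic moments are recovered to machine precision", {
  # build log-paths with exactly the analytic per-time mean and variance
  times <- seq(0, 2, length.out = 5)
  n <- 50
  z <- scale(seq_len(n))[, 1]          # mean 0, sample variance 1 exactly
  rate <- ref_rate()
  init <- ref_point_initial()
  lp <- vapply(times, function(t) {
    p <- evolve_log_params(init, rate, t)
    p$mu + sqrt(p$sigma2) * z
  }, numeric(n))
  ens <- lognormkin:::new_ensemble(times, exp(lp), rate, noise_spec(0),
                                   "analytic", init)
  rec <- recover_kinetics(ens, n_boot = 0)
  expect_equal(rec$mu_k_hat, 1, tolerance = 1e-10)
  expect_equal(rec$sigma_k2_hat, 0.25, tolerance = 1e-10)
})

test_that("kinetic parameters are recovered from simulated ensembles", {
  ens <- simulate_exact(1, ref_rate(), simulation_grid(2, 10), 1e4,
                        noise_spec(21))
  rec <- recover_kinetics(ens, n_boot = 200, boot_seed = 2)
  expect_lt(abs(rec$mu_k_hat - 1), 0.05)
  expect_lt(abs(rec$sigma_k2_hat - 0.25), 0.05 * 0.25)
  # formation ensembles invert with the flipped drift sign
  fens <- simulate_formation(1, rate_model(0.8, 0.4, "formation"),
                             simulation_grid(2, 10), 5e3, noise_spec(22))
  frec <- recover_kinetics(fens, n_boot = 0)
  expect_lt(abs(frec$mu_k_hat - 0.8), 0.05)
})

test_that("bootstrap intervals cover the true parameters at a sane rate", {
  hits <- vapply(1:10, function(s) {
    ens <- simulate_exact(1, ref_rate(), simulation_grid(2, 10), 2000,
                          noise_spec(800 + s))
    rec <- recover_kinetics(ens, n_boot = 100, boot_seed = s)
    c(rec$ci["mu_k", 1] <= 1 && 1 <= rec$ci["mu_k", 2],
      rec$ci["sigma_k2", 1] <= 0.25 && 0.25 <= rec$ci["sigma_k2", 2])
  }, logical(2))
  # nominal 95% intervals: demand at least 7/10 hits per parameter
  expect_gte(sum(hits[1, ]), 7)
  expect_gte(sum(hits[2, ]), 7)
})

test_that("a deterministic ensemble is flagged as zero-noise", {
  ens <- simulate_exact(1, rate_model(1, 0), simulation_grid(1, 5), 100,
                        noise_spec(23))
  rec <- recover_kinetics(ens, n_boot = 0)
  expect_equal(rec$sigma_k2_hat, 0)
  expect_lt(abs(rec$mu_k_hat - 1), 0.01)
})

test_that("recovery error shrinks roughly as one over root n_paths", {
  err <- vapply(c(100, 10000), function(np) {
    e <- vapply(1:5, function(s) {
      ens <- simulate_exact(1, ref_rate(), simulation_grid(2, 10), np,
                            noise_spec(700 + s))
      rec <- recover_kinetics(ens, n_boot = 0)
      abs(rec$sigma_k2_hat - 0.25)
    }, 0)
    mean(e)
  }, 0)
  # a factor 100 in paths should shrink the mean error by well over 3x
  expect_gt(err[1] / err[2], 3)
})

test_that("recovery demands enough structure", {
  ens <- simulate_exact(1, ref_rate(), simulation_grid(1, 1), 100,
                        noise_spec(1))
  expect_error(recover_kinetics(ens), "3 time points")
  ens2 <- simulate_exact(1, ref_rate(), simulation_grid(1, 5), 5,
                         noise_spec(1))
  expect_error(recover_kinetics(ens2), "paths")
})

test_that("ratio and product propagation follow the closed forms", {
  a <- lognormal_params(1, 0.04)
  b <- lognormal_params(0.5, 0.05)
  r <- ratio_params(a, b)
  expect_equal(r$mu, 0.5)
  expect_equal(r$sigma2, 0.09)
  # self-ratio of independent copies
  rr <- ratio_params(a, a)
  expect_equal(rr$mu, 0)
  expect_equal(rr$sigma2, 0.08)
  # degenerate denominator is a pure shift
  expect_equal(ratio_params(a, lognormal_params(2, 0))$mu, -1)

  p <- derived_rate_flux(lognormal_params(0, 0.1), lognormal_params(1, 0.2))
  expect_equal(p$mu, 1)
  expect_equal(p$sigma2, 0.3, tolerance = 1e-12)
  expect_equal(derived_rate_flux(a, 1), a)
  sh <- derived_rate_flux(a, 2)
  expect_equal(sh$mu, 1 + log(2))
  expect_equal(sh$sigma2, 0.04)
  expect_error(derived_rate_flux(a, -1), "proportionality")
})

test_that("products compose associatively and keep variance non-negative", {
  ps <- list(lognormal_params(0.1, 0.2), lognormal_params(-0.4, 0.05),
             lognormal_params(1.2, 0.6))
  left <- derived_rate_flux(derived_rate_flux(ps[[1]], ps[[2]]), ps[[3]])
  right <- derived_rate_flux(ps[[1]], derived_rate_flux(ps[[2]], ps[[3]]))
  expect_equal(left$mu, right$mu)
  expect_equal(left$sigma2, right$sigma2)
  expect_gte(ratio_params(ps[[1]], ps[[3]])$sigma2, 0)
})
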