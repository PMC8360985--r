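test_that("kinetic sampler draws the requested log-normal", {
  n <- 1e5
  x <- sample_kinetic(lognormal_params(0, 1), n, noise_spec(1))
  expect_true(all(x > 0))
  expect_lt(abs(mean(log(x))), se3(1, n))
  expect_lt(abs(var(log(x)) - 1), 3 * sqrt(2 / n))
  # degenerate limit: all samples collapse to exp(mu)
  x0 <- sample_kinetic(lognormal_params(0.7, 0), 10, noise_spec(1))
  expect_equal(x0, rep(exp(0.7), 10))
  expect_error(sample_kinetic(lognormal_params(0, 1), 0, noise_spec(1)), "n")
})

test_that("mixture sampling respects weights and exposes state labels", {
  comps <- list(lognormal_params(-2, 0.04), lognormal_params(0, 0.04),
                lognormal_params(2, 0.04))
  sp1 <- mixture_spec(comps, weights = c(1, 0, 0))
  out <- sample_mixture(sp1, 500, noise_spec(1))
  expect_true(all(out$states == 1L))

  sp <- mixture_spec(comps)
  out <- sample_mixture(sp, 3e4, noise_spec(2))
  expect_true(all(out$samples > 0))
  # closed-form mixture mean: sum w_i exp(mu_i + sigma2_i/2)
  mix_mean <- mean(sapply(comps, lognormal_mean))
  mix_var <- mean(sapply(comps, function(p)
    (exp(p$sigma2) - 1) * exp(2 * p$mu + p$sigma2) + lognormal_mean(p)^2)) -
    mix_mean^2
  expect_lt(abs(mean(out$samples) - mix_mean), se3(sqrt(mix_var), 3e4))
  # three well-separated components give three density modes
  expect_identical(count_density_modes(out$samples), 3L)
  # conditional on the label, each component is log-normal
  for (k in 1:3) {
    ht <- test_lognormality(out$samples[out$states == k], alpha = 0.01)
    expect_identical(ht$decision, "not-reject")
  }
})

test_that("markov switching produces persistent blocks", {
  comps <- list(lognormal_params(-2, 0.04), lognormal_params(2, 0.04))
  expect_error(sample_mixture(mixture_spec(comps), 100, noise_spec(1),
                              mode = "markov"), "persistence")
  sp <- mixture_spec(comps, persistence = 0.95)
  out <- sample_mixture(sp, 5000, noise_spec(3), mode = "markov")
  stay <- mean(out$states[-1] == out$states[-5000])
  expect_gt(stay, 0.9)  # around the stay probability
  expect_true(all(sort(unique(out$states)) == 1:2))
})

test_that("single-component convolution equals the kinetic sampler draw for draw", {
  p <- lognormal_params(0.3, 0.5)
  sp <- mixture_spec(list(p))
  expect_identical(sample_convolution(sp, 1000, noise_spec(4)),
                   sample_kinetic(p, 1000, noise_spec(4)))
})

test_that("convolution of many sources tends towards normality", {
  p <- lognormal_params(0, 0.25)
  K <- 30
  sp <- mixture_spec(replicate_components(p, K))
  n <- 2e4
  x <- sample_convolution(sp, n, noise_spec(5))
  expect_lt(abs(mean(x) - K * lognormal_mean(p)),
            se3(sd(x), n))
  # CLT tendency: skewness of the sum is well below one component's,
  # scaling roughly as K^(-1/2)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  x1 <- sample_kinetic(p, n, noise_spec(6))
  expect_lt(skew(x), skew(x1) / 3)
  expect_error(sample_convolution(mixture_spec(list()), 10, noise_spec(1)),
               "components")
})

test_that("oscillatory modulation adds A^2/2 to the log-variance", {
  base <- lognormal_params(0, 0.04)
  osc <- oscillation_spec(amplitude = 2, period = 1)
  n <- 1e5
  out <- sample_oscillatory(base, osc, n, noise_spec(7))
  expect_true(all(out$samples > 0))
  expect_true(all(out$times >= 0 & out$times <= 1))
  lx <- log(out$samples)
  v <- var(lx)
  se_v <- sd((lx - mean(lx))^2) / sqrt(n)
  expect_lt(abs(v - (0.04 + 2^2 / 2)), 3 * se_v)
})

test_that("zero amplitude reduces bit-exactly to the kinetic sampler", {
  base <- lognormal_params(0.2, 0.3)
  out <- sample_oscillatory(base, oscillation_spec(0, 1), 1000, noise_spec(8))
  expect_identical(out$samples, sample_kinetic(base, 1000, noise_spec(8)))
})

test_that("strong modulation against weak noise defeats log-normality", {
  base <- lognormal_params(0, 0.04)
  osc <- oscillation_spec(2, 1)
  rejected <- vapply(1:20, function(s) {
    out <- sample_oscillatory(base, osc, 5000, noise_spec(300 + s))
    test_lognormality(out$samples, alpha = 0.01)$decision == "reject"
  }, TRUE)
  expect_true(all(rejected))  # bimodal log-marginal at A/sigma = 10
})

test_that("mode counting is calibrated on unimodal and bimodal samples", {
  x <- sample_kinetic(lognormal_params(0, 0.25), 2e4, noise_spec(9))
  expect_identical(count_density_modes(x), 1L)
  sp <- mixture_spec(list(lognormal_params(-2, 0.04),
                          lognormal_params(2, 0.04)))
  y <- sample_mixture(sp, 2e4, noise_spec(10))$samples
  expect_identical(count_density_modes(y), 2L)
})

test_that("generators are deterministic under a fixed seed", {
  sp <- mixture_spec(list(lognormal_params(-1, 0.1), lognormal_params(1, 0.1)))
  expect_identical(sample_mixture(sp, 100, noise_spec(11)),
                   sample_mixture(sp, 100, noise_spec(11)))
  expect_identical(sample_convolution(sp, 100, noise_spec(11)),
                   sample_convolution(sp, 100, noise_spec(11)))
  o1 <- sample_oscillatory(lognormal_params(0, 0.1), oscillation_spec(1, 2),
                           100, noise_spec(11))
  o2 <- sample_oscillatory(lognormal_params(0, 0.1), oscillation_spec(1, 2),
                           100, noise_spec(11))
  expect_identical(o1, o2)
})

test_that("mixture specifications validate weights and persistence", {
  comps <- list(lognormal_params(0, 1))
  expect_error(mixture_spec(comps, weights = c(0.5, 0.5)), "weights")
  expect_error(mixture_spec(comps, weights = 2), "sum to 1")
  expect_error(mixture_spec(comps, persistence = 1), "persistence")
  expect_error(mixture_spec(list(1, 2)), "lognormal_params")
  expect_error(oscillation_spec(-1, 1), "amplitude")
  expect_error(oscillation_spec(1, 0), "period")
})
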