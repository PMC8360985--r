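test_that("zero noise reduces both schemes to deterministic decay", {
  grid <- simulation_grid(1, 100)
  rate <- rate_model(1, 0)
  ex <- simulate_exact(1, rate, grid, 5, noise_spec(1))
  expect_equal(ex$paths, matrix(exp(-grid$times), 5, 101, byrow = TRUE))
  em <- simulate_euler_maruyama(1, rate, grid, 5, noise_spec(1))
  # Euler limit: O(dt) relative error at the terminal time
  expect_equal(em$paths[1, 101], exp(-1), tolerance = 2 * grid$dt)
})

test_that("exact sampler marginals match the evolved log-normal", {
  n <- 1e5
  ens <- simulate_exact(1, ref_rate(), simulation_grid(1, 4), n, noise_spec(2))
  lx <- log(ens$paths[, 5])
  expect_lt(abs(mean(lx) - (-1.125)), se3(0.5, n))
  expect_lt(abs(var(lx) - 0.25), 3 * 0.25 * sqrt(2 / n))
  # distributional agreement at the terminal time
  ks <- suppressWarnings(ks.test(lx, "pnorm", -1.125, 0.5))
  expect_lt(unname(ks$statistic), 0.01)
  expect_true(all(ens$paths > 0))
})

test_that("paths are temporally consistent, not redrawn per time point", {
  ens <- simulate_exact(1, ref_rate(), simulation_grid(1, 50), 2000,
                        noise_spec(3))
  # log-increments of one path over adjacent times have variance
  # sigma_k^2 dt, and the path correlates strongly across adjacent times
  dlx <- diff(log(ens$paths[1, ]))
  expect_equal(var(dlx), 0.25 * 0.02, tolerance = 0.5)
  r <- cor(log(ens$paths[, 50]), log(ens$paths[, 51]))
  expect_gt(r, 0.95)
})

test_that("log-normal initial spread is honoured at the start time", {
  init <- lognormal_params(0.5, 0.09)
  ens <- simulate_exact(init, ref_rate(), simulation_grid(1, 2), 5e4,
                        noise_spec(4))
  l0 <- log(ens$paths[, 1])
  expect_lt(abs(mean(l0) - 0.5), se3(0.3, 5e4))
  expect_lt(abs(var(l0) - 0.09), 3 * 0.09 * sqrt(2 / 5e4))
})

test_that("identical configuration and seed reproduce identical ensembles", {
  g <- simulation_grid(1, 20)
  a <- simulate_exact(1, ref_rate(), g, 50, noise_spec(7))
  b <- simulate_exact(1, ref_rate(), g, 50, noise_spec(7))
  expect_identical(a$paths, b$paths)
  c <- simulate_euler_maruyama(1, ref_rate(), g, 50, noise_spec(7))
  d <- simulate_euler_maruyama(1, ref_rate(), g, 50, noise_spec(7))
  expect_identical(c$paths, d$paths)
  # different seeds differ
  e <- simulate_exact(1, ref_rate(), g, 50, noise_spec(8))
  expect_false(identical(a$paths, e$paths))
})

test_that("Euler-Maruyama converges weakly to the evolved log-normal", {
  n <- 1e5
  dt <- 1e-3
  em <- simulate_euler_maruyama(1, ref_rate(), simulation_grid(1, 1 / dt), n,
                                noise_spec(5))
  lx <- log(em$paths[, ncol(em$paths)])
  # O(dt) weak bias allowance on top of 3 SE
  bias <- (ref_rate()$mu_k^2 / 2 + ref_rate()$mu_k * 0.25 + 0.75 * 0.25^2) * dt
  expect_lt(abs(mean(lx) - (-1.125)), se3(0.5, n) + 2 * bias)
  expect_lt(abs(var(lx) - 0.25), 3 * 0.25 * sqrt(2 / n) + 2 * bias)
  expect_true(all(em$paths > 0))
})

test_that("Euler-Maruyama refuses an unstable step and suggests n_steps", {
  err <- tryCatch(
    simulate_euler_maruyama(1, rate_model(5, 0.1), simulation_grid(1, 4), 10,
                            noise_spec(1)),
    error = function(e) conditionMessage(e))
  expect_match(err, "stability guard")
  expect_match(err, "n_steps")
})

test_that("Euler-Maruyama terminal law approaches the exact sampler as dt shrinks", {
  ref <- log(simulate_exact(1, ref_rate(), simulation_grid(1, 1), 5e4,
                            noise_spec(100))$paths[, 2])
  ks_at <- function(n_steps, seed) {
    em <- simulate_euler_maruyama(1, ref_rate(), simulation_grid(1, n_steps),
                                  5e3, noise_spec(seed))
    unname(suppressWarnings(
      ks.test(log(em$paths[, n_steps + 1]), ref)$statistic))
  }
  mean_ks <- vapply(c(10, 1000), function(ns)
    mean(vapply(1:3, function(s) ks_at(ns, 200 + s), 0)), 0)
  expect_gt(mean_ks[1], mean_ks[2])
})

test_that("formation ensembles grow log-normally with the same variance law", {
  rate <- rate_model(1, 0.5, "formation")
  n <- 5e4
  ens <- simulate_formation(1, rate, simulation_grid(1, 4), n, noise_spec(6))
  lx <- log(ens$paths[, 5])
  expect_lt(abs(var(lx) - 0.25), 3 * 0.25 * sqrt(2 / n))
  expect_lt(abs(mean(lx) - (1 - 0.125)), se3(0.5, n))
  # arithmetic mean grows as exp(+mu_k t)
  m <- colMeans(ens$paths)
  expect_true(all(diff(m) > 0))
  expect_equal(m[5], exp(1), tolerance = 0.05)
  # sigma_k = 0: deterministic exponential growth
  det <- simulate_formation(2, rate_model(0.7, 0, "formation"),
                            simulation_grid(1, 10), 3, noise_spec(1))
  expect_equal(det$paths[2, ], 2 * exp(0.7 * det$times))
})

test_that("formation terminal marginals pass the log-normality screen", {
  # exact sampler marginals are log-normal by construction; the test-level
  # rejection rate at alpha = 0.01 stays near its nominal level
  rate <- rate_model(1, 0.5, "formation")
  grid <- simulation_grid(1, 2)
  pass <- vapply(1:100, function(s) {
    ens <- simulate_formation(1, rate, grid, 400, noise_spec(1000 + s))
    test_lognormality(ens$paths[, 3], alpha = 0.01)$decision == "not-reject"
  }, TRUE)
  expect_gte(sum(pass), 95)
})
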