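# shared fixtures, built in code

ref_rate <- function(direction = "sink") rate_model(1, 0.5, direction)
ref_point_initial <- function() lognormal_params(mu = 0, sigma2 = 0)

# ensemble used across simulator/recovery tests: mu_k = 1, sigma_k = 0.5,
# point initial X(0) = 1, 11 times on [0, 2]
ref_ensemble <- function(n_paths = 2000, seed = 42) {
  simulate_exact(1, ref_rate(), simulation_grid(2, 10), n_paths,
                 noise_spec(seed))
}

# 3 SE bound for a sample mean of n draws with sd s
se3 <- function(s, n) 3 * s / sqrt(n)

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent trapezoidal quadrature used to check densities
trapz_ref <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
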