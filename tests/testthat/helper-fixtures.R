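# Shared fixtures: all synthetic, generated in code at test time.

# Small default-config population.
small_pop <- function(n = 400, seed = 1) {
  cfg <- population_config(n_cases = n, seed = seed)
  generate_population(cfg)
}

# Two-group exponential survival data with known log hazard ratio.
toy_exp_data <- function(n = 200, beta = 0.7, seed = 1, censor_at = Inf) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = exp(beta * x))
  data.frame(x = x, time = pmin(t, censor_at),
             event = as.integer(t <= censor_at))
}

# Random small survival dataset with ties, for oracle comparisons.
random_surv_data <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- runif(p, -1, 1)
  t <- round(rexp(n, rate = exp(drop(X %*% beta))), 1) + 0.05
  cens <- rexp(n, rate = 0.3)
  data.frame(X, time = pmin(t, cens), event = as.integer(t <= cens))
}
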