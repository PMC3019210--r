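test_that("skew-normal parameter solver reproduces the requested moments", {
  prm <- skew_normal_params(61, 9.95, -0.67)
  set.seed(1)
  x <- sample_skewed_age(prm, 2e5)
  expect_equal(mean(x), 61, tolerance = 0.005)
  expect_equal(sd(x), 9.95, tolerance = 0.01)
  expect_equal(sample_skewness(x), -0.67, tolerance = 0.05)
  # symmetric limit
  sym <- skew_normal_params(0, 1, 0)
  expect_equal(sym$alpha, 0)
  set.seed(2)
  expect_lt(abs(sample_skewness(sample_skewed_age(sym, 1e5))), 0.05)
  expect_error(skew_normal_params(0, 1, 1.2), "skew")
})

test_that("phi correlation matches the 2x2 closed form", {
  expect_equal(phi_correlation(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  tab <- function(a, b, c, d) {
    x <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
    y <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
    phi_correlation(x, y)
  }
  expect_equal(tab(25, 25, 25, 25), 0.0)
  expect_equal(tab(40, 10, 10, 40), 0.6)
  expect_error(phi_correlation(c(1, 1, 1), c(0, 1, 0)), "constant")
})

test_that("latent correlation solver hits phi targets and flags infeasible ones", {
  for (case in list(c(-0.72, 0.497, 0.425), c(0.32, 0.31, 0.048),
                    c(0.42, 0.31, 0.133))) {
    rho <- latent_rho_for_phi(case[1], case[2], case[3])
    expect_equal(coxmiss:::phi_from_latent(rho, case[2], case[3]), case[1],
                 tolerance = 1e-7)
  }
  # phi = 0.5 exceeds the Frechet bound for a 95:5 vs 50:50 split
  expect_error(latent_rho_for_phi(0.5, 0.05, 0.5, pair = "pre_rt~stage"),
               "pre_rt~stage")
})

test_that("generated populations match configured marginals and codes", {
  cfg <- population_config(n_cases = 20000, seed = 3)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 20000)
  expect_false(anyNA(pop))
  expect_true(all(pop$time > 0))
  expect_true(all(pop$event %in% c(0L, 1L)))
  expect_named(pop, c(covariate_names(), "time", "event"))
  for (v in names(cfg$binary_marginals)) {
    expect_true(all(pop[[v]] %in% c(0L, 1L)))
    p <- cfg$binary_marginals[[v]]
    mc_se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(mean(pop[[v]]) - p), 3.5 * mc_se)
  }
})

test_that("null coefficients without censoring give 100% events and no covariate effect", {
  cfg <- population_config(
    n_cases = 5000,
    beta_gen = setNames(rep(0, 8), covariate_names()),
    baseline_hazard = list(shape = 1.5, scale = 2, cure = 0),
    censoring = NULL, seed = 4)
  pop <- generate_population(cfg)
  expect_true(all(pop$event == 1L))
  # survival independent of stage: compare KM at the median time
  t0 <- median(pop$time)
  s1 <- km_survival_at(pop$time[pop$stage == 1], pop$event[pop$stage == 1], t0)
  s0 <- km_survival_at(pop$time[pop$stage == 0], pop$event[pop$stage == 0], t0)
  expect_lt(abs(s1 - s0), 0.04)
})

test_that("with zero coefficients the KM curve matches the closed-form baseline", {
  cure <- 0.784585
  cfg <- population_config(
    n_cases = 50000,
    beta_gen = setNames(rep(0, 8), covariate_names()),
    seed = 5)
  pop <- generate_population(cfg)
  s0 <- function(t) cure + (1 - cure) * exp(-(t / 1.906245)^1.546221)
  for (t in c(1, 3, 6)) {
    km <- km_survival_at(pop$time, pop$event, t)
    expect_equal(km, s0(t), tolerance = 0.01)
  }
})

test_that("Kaplan-Meier estimator agrees with hand and reference values", {
  expect_equal(km_survival_at(c(1, 2, 3), c(1, 1, 1), 0), 1.0)
  expect_equal(km_survival_at(c(1, 2, 3), c(1, 1, 1), 1.5), 2 / 3)
  skip_if_not_installed("survival")
  set.seed(6)
  tm <- round(rexp(300, 0.4), 1) + 0.1
  ev <- rbinom(300, 1, 0.6)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  for (t in c(0.5, 1.7, 4.1)) {
    ref <- summary(sf, times = t)$surv
    expect_equal(km_survival_at(tm, ev, t), ref, tolerance = 1e-12)
  }
  expect_error(km_survival_at(numeric(0), numeric(0), 1))
})

test_that("bootstrap sampling is uniform-with-replacement and reproducible", {
  pop1 <- small_pop(10, seed = 7)[1, , drop = FALSE]
  smp <- draw_bootstrap_sample(pop1, 5)
  expect_equal(nrow(smp), 5)
  expect_true(all(duplicated(smp)[-1]))
  pop <- small_pop(300, seed = 8)
  set.seed(11); a <- draw_bootstrap_sample(pop, 50)
  set.seed(11); b <- draw_bootstrap_sample(pop, 50)
  expect_identical(a, b)
  # unbiasedness of resample means over 500 draws
  set.seed(12)
  means <- replicate(500, mean(draw_bootstrap_sample(pop, 100)$age))
  se <- sd(pop$age) / sqrt(100) / sqrt(500)
  expect_lt(abs(mean(means) - mean(pop$age)), 4 * se)
})
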