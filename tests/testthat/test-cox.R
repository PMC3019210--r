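test_that("fit_cox matches the reference implementation on random datasets", {
  skip_if_not_installed("survival")
  for (s in 1:50) {
    d <- random_surv_data(n = sample(40:90, 1), p = sample(2:3, 1), seed = s)
    covs <- grep("^x", names(d), value = TRUE)
    fit <- fit_cox(d, covariates = covs, tol = 1e-12)
    ref <- suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ .,
      data = d[, c(covs, "time", "event")], ties = "efron",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(fit$loglik_fit, ref$loglik[2], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
  }
})

test_that("Breslow tie handling also matches the reference", {
  skip_if_not_installed("survival")
  for (s in 1:10) {
    d <- random_surv_data(n = 60, p = 2, seed = 100 + s)
    fit <- fit_cox(d, covariates = c("x1", "x2"), ties = "breslow",
                   tol = 1e-12)
    ref <- suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ x1 + x2, data = d, ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  }
})

test_that("fit invariants hold: vcov psd, loglik ordering, se consistency", {
  d <- random_surv_data(n = 200, p = 3, seed = 7)
  fit <- fit_cox(d, covariates = c("x1", "x2", "x3"))
  expect_true(fit$converged)
  expect_gte(fit$loglik_fit, fit$loglik_null)
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
  expect_equal(fit$se, sqrt(diag(fit$vcov)))
  expect_equal(fit$linear_predictor,
               drop(as.matrix(d[, c("x1", "x2", "x3")]) %*% fit$beta))
})

test_that("a permuted covariate gets a near-zero coefficient", {
  set.seed(8)
  d <- random_surv_data(n = 1500, p = 2, seed = 8)
  d$x2 <- sample(d$x2)
  fit <- fit_cox(d, covariates = c("x1", "x2"))
  z <- fit$beta["x2"] / fit$se["x2"]
  expect_lt(abs(z), 3.5)
})

test_that("two-group exponential data recover the log rate ratio", {
  d <- toy_exp_data(n = 4000, beta = 0.7, seed = 9)
  fit <- fit_cox(d, covariates = "x")
  # closed-form exponential MLE oracle: log((d1/T1)/(d0/T0))
  mle <- log((sum(d$event[d$x == 1]) / sum(d$time[d$x == 1])) /
               (sum(d$event[d$x == 0]) / sum(d$time[d$x == 0])))
  expect_equal(unname(fit$beta), mle, tolerance = 0.05)
  expect_equal(unname(fit$beta), 0.7, tolerance = 0.1)
})

test_that("monotone likelihood is flagged as non-converged", {
  # all exposed cases fail before any unexposed case: beta diverges
  d <- data.frame(x = rep(c(1, 0), each = 20),
                  time = c(seq(1, 2, length.out = 20),
                           seq(3, 4, length.out = 20)),
                  event = 1L)
  fit <- fit_cox(d, covariates = "x")
  expect_false(fit$converged)
})

test_that("constant covariates and event-free data are rejected", {
  d <- toy_exp_data(n = 50, seed = 10)
  d$cst <- 1
  expect_error(fit_cox(d, covariates = c("x", "cst")), "constant")
  d$event <- 0L
  expect_error(fit_cox(d, covariates = "x"), "event")
})
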