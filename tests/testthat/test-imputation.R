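ampute_small <- function(n = 300, p0 = 0.4, seed = 51) {
  pop <- small_pop(n, seed = seed)
  impose_mar(pop, config = amputation_config(p0, seed = seed + 1))
}

test_that("complete-case filter drops exactly the masked rows unchanged", {
  pop <- small_pop(5, seed = 52)
  inc <- pop
  inc$stage[c(2, 4)] <- NA
  cc <- complete_case_filter(inc)
  expect_equal(nrow(cc), 3)
  expect_equal(cc, local({x <- pop[c(1, 3, 5), ]; rownames(x) <- NULL; x}))
  inc$stage <- NA
  expect_error(complete_case_filter(inc), "infeasible")
  expect_identical(complete_case_filter(pop), pop)
  # amputation at rate p0 retains exactly 1 - p0 of cases
  inc2 <- ampute_small(n = 400, p0 = 0.25)
  expect_equal(nrow(complete_case_filter(inc2)), 300)
})

test_that("PMM imputes the nearest donors' observed values", {
  # single donor: always that value
  expect_equal(pmm_impute_column(2L, c(5, 99, 7), c(10, 20), k = 1)
               %in% c(10, 20), TRUE)
  # hand-enumerated nearest neighbour
  set.seed(53)
  out <- pmm_impute_column(4L, c(1.0, 2.0, 3.0, 1.1), c(1, 2, 3), k = 1)
  expect_equal(out, 1)
  # closure: imputed values live in the observed support
  set.seed(54)
  preds <- rnorm(60)
  obs_vals <- round(rnorm(40), 2)
  got <- pmm_impute_column(41:60, preds, obs_vals, k = 3)
  expect_true(all(got %in% obs_vals))
  # pool shrinks with a warning when donors are scarce
  expect_warning(pmm_impute_column(3:6, rnorm(6), c(1, 2), k = 5), "shrunk")
})

test_that("pmm_match always selects within the brute-force k-nearest pool", {
  set.seed(55)
  for (rep in 1:20) {
    pred_obs <- rnorm(30)
    vals <- seq_along(pred_obs) * 10
    pm <- rnorm(1)
    k <- sample(1:4, 1)
    got <- coxmiss:::pmm_match(pm, pred_obs, vals, k)
    pool <- vals[order(abs(pred_obs - pm))[1:k]]
    expect_true(got %in% pool)
  }
})

test_that("chained engines preserve observed entries bit-exactly", {
  inc <- ampute_small()
  for (engine in c("SI", "MICE", "MICE-PMM", "AREG-PMM")) {
    cfg <- imputation_config(engine, m = 2, n_cycles = 2, seed = 61)
    outs <- impute_missing(inc, cfg)
    expect_length(outs, if (engine == "SI") 1 else 2)
    for (out in outs) {
      expect_false(anyNA(out))
      obs <- !is.na(inc)
      expect_identical(as.matrix(out)[obs], as.matrix(inc)[obs])
      expect_true(all(out$stage %in% c(0, 1)))
      expect_true(all(out$post_rt %in% c(0, 1)))
    }
  }
})

test_that("PMM-imputed ages come from the observed support; MI varies, SI does not", {
  inc <- ampute_small(n = 400, p0 = 0.5, seed = 62)
  mi <- chained_impute(inc, imputation_config("MICE-PMM", m = 3,
                                              n_cycles = 2, seed = 63))
  miss_age <- which(is.na(inc$age))
  obs_age <- inc$age[!is.na(inc$age)]
  for (out in mi) expect_true(all(out$age[miss_age] %in% obs_age))
  # between-imputation variability is genuine
  imp_mat <- sapply(mi, function(d) d$age[miss_age])
  expect_gt(max(apply(imp_mat, 1, sd)), 0)
  si <- chained_impute(inc, imputation_config("SI", seed = 64))
  expect_length(si, 1)
})

test_that("complete input passes through every engine unchanged", {
  pop <- small_pop(100, seed = 65)
  for (engine in c("SI", "MICE", "MICE-PMM", "AREG-PMM")) {
    outs <- impute_missing(pop, imputation_config(engine, m = 2, seed = 66))
    for (out in outs) {
      expect_identical(out[, names(pop)], pop)
    }
  }
})

test_that("the spline basis nests a linear relationship exactly", {
  set.seed(67)
  x <- rnorm(200)
  y <- 2 * x + 1
  B <- cbind(1, coxmiss:::rcs_basis(x, 3))
  resid <- y - B %*% solve(crossprod(B) + diag(1e-12, ncol(B)),
                           crossprod(B, y))
  expect_lt(max(abs(resid)), 1e-8)
  # knot collapse on tie-heavy data degrades gracefully
  expect_warning(coxmiss:::rcs_basis(rep(c(1, 1, 1, 2), 25), 3), "collapsed")
})

test_that("duplicate-heavy bootstrap samples still impute under AREG-PMM", {
  inc <- ampute_small(n = 200, p0 = 0.3, seed = 68)
  dup <- inc[rep(1:50, 4), ]
  rownames(dup) <- NULL
  outs <- areg_impute(dup, imputation_config("AREG-PMM", m = 2,
                                             n_cycles = 2, seed = 69))
  for (out in outs) expect_false(anyNA(out))
})

test_that("MI relative efficiency follows (1 + gamma/m)^-1", {
  expect_equal(mi_relative_efficiency(0.5, 10), 1 / 1.05)
  expect_equal(mi_relative_efficiency(0, 5), 1)
  # 10 imputations retain ~95% efficiency at 50% missing information
  expect_gt(mi_relative_efficiency(0.5, 10), 0.95)
})

test_that("proper MI beats single imputation on coverage under heavy MAR", {
  # scaled-down toy: age-dominated missingness at p0 = 0.5
  set.seed(71)
  n_reps <- 60
  truth_pop <- generate_population(population_config(n_cases = 20000,
                                                     seed = 72))
  truth_fit <- fit_cox(truth_pop)
  beta_age <- unname(truth_fit$beta["age"])
  cover <- function(engine, m) {
    hits <- 0L
    used <- 0L
    for (i in seq_len(n_reps)) {
      smp <- draw_bootstrap_sample(truth_pop, 350)
      inc <- impose_mar(smp, config = amputation_config(0.5))
      outs <- suppressWarnings(
        impute_missing(inc, imputation_config(engine, m = m, n_cycles = 3)))
      fits <- lapply(outs, function(d) tryCatch(fit_cox(d),
                                                error = function(e) NULL))
      fits <- Filter(function(f) !is.null(f) && f$converged, fits)
      if (length(fits) == 0) next
      pe <- rubin_pool(sapply(fits, function(f) f$beta["age"]),
                       sapply(fits, function(f) f$se["age"]^2))
      used <- used + 1L
      if (pe$ci[1] <= beta_age && beta_age <= pe$ci[2]) hits <- hits + 1L
    }
    hits / used
  }
  expect_gte(cover("MICE-PMM", 5), cover("SI", 1))
})
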