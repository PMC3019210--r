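test_that("packaged pattern table satisfies its invariants", {
  pt <- default_pattern_table()
  expect_equal(sum(pt$p), 1, tolerance = 1e-12)
  expect_true(all(rowSums(pt$patterns) < 3))
  expect_equal(unname(pt$patterns[7, ]), c(0, 0, 0))
  expect_equal(expected_missing_items(pt), 1.58)
  # implied per-covariate missingness among incomplete cases
  expect_equal(sum(pt$p[pt$patterns[, "stage"] == 0]), 0.71)
  expect_error(pattern_table(rbind(c(1, 1, 1)), 1), "all-observed|observed")
})

test_that("amputation masks exactly round(p0 n) cases with table patterns", {
  pop <- small_pop(400, seed = 21)
  pt <- default_pattern_table()
  for (p0 in c(0.05, 0.25, 0.6)) {
    out <- impose_mar(pop, pt, amputation_config(p0, seed = 31))
    mask <- is.na(out[, c("stage", "post_rt", "age")])
    expect_equal(sum(rowSums(mask) > 0), round(p0 * 400))
    # no other column is ever masked
    expect_false(anyNA(out[, setdiff(names(out),
                                     c("stage", "post_rt", "age"))]))
    # every realized mask is one of the seven patterns
    pat <- unique(apply((1 - mask)[rowSums(mask) > 0, , drop = FALSE], 1,
                        paste, collapse = ""))
    legal <- apply(pt$patterns, 1, paste, collapse = "")
    expect_true(all(pat %in% legal))
  }
  expect_error(impose_mar(pop, pt, amputation_config(0.001, seed = 1)),
               "zero")
})

test_that("realized pattern frequencies converge to the table probabilities", {
  pop <- small_pop(20000, seed = 22)
  out <- impose_mar(pop, config = amputation_config(0.5, seed = 32))
  sm <- missingness_summary(out)
  expect_equal(sm$p0, 0.5, tolerance = 1e-9)
  pt <- default_pattern_table()
  labels <- apply(pt$patterns, 1, paste, collapse = "")
  n_inc <- sm$n_incomplete
  for (i in seq_along(labels)) {
    realized <- unname(sm$pattern_frequencies[labels[i]])
    mc_se <- sqrt(pt$p[i] * (1 - pt$p[i]) / n_inc)
    expect_lt(abs(realized - pt$p[i]), 3.5 * mc_se)
  }
  # stage missing among incomplete cases: 71%
  expect_equal(unname(sm$pct_missing_of_incomplete["stage"]), 71,
               tolerance = 2)
})

test_that("available-item fraction matches the 1 - p0*1.58/8 oracle", {
  # brute-force oracle: expectation over pattern draws
  pt <- default_pattern_table()
  oracle <- function(p0) 100 * (1 - p0 * sum(pt$p * rowSums(1 - pt$patterns)) / 8)
  pop <- small_pop(2000, seed = 23)
  set.seed(33)
  for (p0 in c(0.05, 0.5)) {
    av <- replicate(30, {
      missingness_summary(
        impose_mar(pop, config = amputation_config(p0)))$pct_items_available
    })
    expect_equal(mean(av), oracle(p0), tolerance = 0.15)
  }
})

test_that("selection is MAR: independent of sex, pre_rt and ct_sch", {
  pop <- small_pop(600, seed = 24)
  shuffled <- pop
  set.seed(41)
  for (v in c("sex", "pre_rt", "ct_sch")) {
    shuffled[[v]] <- sample(shuffled[[v]])
  }
  a <- impose_mar(pop, config = amputation_config(0.3, seed = 42))
  b <- impose_mar(shuffled, config = amputation_config(0.3, seed = 42))
  expect_identical(which(rowSums(is.na(a)) > 0), which(rowSums(is.na(b)) > 0))
})

test_that("MAR direction: incomplete cases are older and die sooner", {
  pop <- small_pop(5000, seed = 25)
  out <- impose_mar(pop, config = amputation_config(0.4, seed = 43))
  sm <- missingness_summary(out)
  expect_gt(sm$mar_diagnostics$mean_age_incomplete,
            sm$mar_diagnostics$mean_age_complete)
  expect_lt(sm$mar_diagnostics$median_time_incomplete,
            sm$mar_diagnostics$median_time_complete)
})

test_that("missingness summary of complete data is degenerate", {
  pop <- small_pop(50, seed = 26)
  sm <- missingness_summary(pop)
  expect_equal(sm$p0, 0)
  expect_equal(sm$pct_items_available, 100)
})
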