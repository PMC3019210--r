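# Orchestration of the factorial resampling study: bootstrap samples
# from one synthetic population, amputation at each missingness rate,
# every missing-data method on the same samples, Cox fits, pooling and
# evaluation.  All randomness flows through per-(replication, stage)
# seed streams derived from the master seed, so replications are
# order-independent and the whole study is reproducible.

# Deterministic 31-bit seed stream keyed by the master seed and any
# number of integer/string identifiers.
derive_seed <- function(master, ...) {
  ids <- c(master, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
  })))
  h <- 5381
  for (v in ids) {
    h <- (h * 69069 + v * 2654435761 + 1013904223) %% 2147483629
  }
  as.integer(h %% 2147483629 + 1)
}

#' Configuration of the full resampling study
#'
#' Defaults mirror the benchmark design: samples of 1000 cases drawn
#' with replacement from the synthetic population, 500 replications,
#' missingness rates 5/10/25/50/75%, all five methods applied to the
#' same samples, 10 imputations per MI method, and truth values from
#' complete-data replications.
#'
#' @param population A [population_config()].
#' @param n_sample Cases per bootstrap sample (default 1000).
#' @param n_replications Number of replications (default 500).
#' @param p0_grid Incomplete-case fractions (default
#'   `c(0.05, 0.10, 0.25, 0.50, 0.75)`).
#' @param methods Engines to compare (default all five).
#' @param m Imputations per MI engine (default 10).
#' @param n_cycles Chained-equation sweeps (default 5).
#' @param donor_pool_k PMM donor-pool size (default 3).
#' @param truth_replications Complete-data replications defining the
#'   truth values (default 2000 for desk use; the full design uses
#'   20000).
#' @param pred_times Prediction horizons in years (default `c(2, 5)`).
#' @param seed Master seed (default 1).
#' @return Object of class `study_config`.
#' @export
study_config <- function(population = population_config(),
                         n_sample = 1000,
                         n_replications = 500,
                         p0_grid = c(0.05, 0.10, 0.25, 0.50, 0.75),
                         methods = c("CC", "SI", "MICE", "MICE-PMM",
                                     "AREG-PMM"),
                         m = 10, n_cycles = 5, donor_pool_k = 3,
                         truth_replications = 2000,
                         pred_times = c(2, 5),
                         seed = 1) {
  stopifnot(n_sample >= 10, n_replications >= 1,
            all(p0_grid > 0), all(p0_grid < 1),
            all(methods %in% c("CC", "SI", "MICE", "MICE-PMM", "AREG-PMM")),
            truth_replications >= 2)
  structure(list(population = population, n_sample = n_sample,
                 n_replications = n_replications, p0_grid = p0_grid,
                 methods = methods, m = m, n_cycles = n_cycles,
                 donor_pool_k = donor_pool_k,
                 truth_replications = truth_replications,
                 pred_times = pred_times, seed = seed),
            class = "study_config")
}

# Fit the Cox model and compute performance measures for one completed
# dataset; never throws.
fit_and_measure <- function(data, pred_times) {
  res <- tryCatch({
    fit <- fit_cox(data)
    surv <- vapply(pred_times, function(t) {
      tryCatch(predicted_survival(fit, t = t), error = function(e) NA_real_)
    }, numeric(1))
    list(fit = fit,
         r2 = nagelkerke_r2(fit),
         d = royston_d(fit$linear_predictor, data$time, data$event),
         surv = surv,
         error = NA_character_)
  }, error = function(e) {
    list(fit = NULL, r2 = NA_real_, d = NA_real_,
         surv = rep(NA_real_, length(pred_times)),
         error = conditionMessage(e))
  })
  res
}

# Pool one method's completed-dataset analyses into coefficient rows
# and one performance row.
pool_method_results <- function(measures, method, p0, replication,
                                pred_times) {
  fits <- Filter(function(m) !is.null(m$fit) && m$fit$converged, measures)
  covs <- covariate_names()
  if (length(fits) == 0) {
    coef_rows <- data.frame(method = method, p0 = p0,
                            replication = replication, covariate = covs,
                            estimate = NA_real_, se = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p = NA_real_, converged = FALSE)
    perf <- data.frame(method = method, p0 = p0, replication = replication,
                       r2 = NA_real_, r2_iqr_lower = NA_real_,
                       r2_iqr_upper = NA_real_, d = NA_real_,
                       converged = FALSE)
    for (i in seq_along(pred_times)) {
      perf[[paste0("surv", pred_times[i])]] <- NA_real_
    }
    return(list(coefficients = coef_rows, performance = perf))
  }
  est <- vapply(fits, function(m) m$fit$beta, numeric(length(covs)))
  vars <- vapply(fits, function(m) m$fit$se^2, numeric(length(covs)))
  est <- matrix(est, nrow = length(covs))
  vars <- matrix(vars, nrow = length(covs))
  coef_rows <- do.call(rbind, lapply(seq_along(covs), function(j) {
    pe <- rubin_pool(est[j, ], vars[j, ])
    data.frame(method = method, p0 = p0, replication = replication,
               covariate = covs[j], estimate = pe$q_bar, se = pe$se,
               ci_lower = pe$ci[1], ci_upper = pe$ci[2], p = pe$p,
               converged = TRUE)
  }))
  r2s <- vapply(fits, function(m) m$r2, numeric(1))
  ds <- vapply(fits, function(m) m$d, numeric(1))
  r2p <- pool_performance(r2s, "r2")
  perf <- data.frame(method = method, p0 = p0, replication = replication,
                     r2 = r2p$value, r2_iqr_lower = r2p$iqr[1],
                     r2_iqr_upper = r2p$iqr[2],
                     d = pool_performance(ds, "d"), converged = TRUE)
  for (i in seq_along(pred_times)) {
    sv <- vapply(fits, function(m) m$surv[i], numeric(1))
    sv <- sv[is.finite(sv) & sv > 0 & sv < 1]
    perf[[paste0("surv", pred_times[i])]] <-
      if (length(sv) == 0) NA_real_ else pool_performance(sv, "survival")
  }
  list(coefficients = coef_rows, performance = perf)
}

#' Truth run: complete-data replications
#'
#' Draws `truth_replications` bootstrap samples from the population,
#' fits the eight-covariate Cox model to each (no missingness), and
#' returns the mean coefficients, their empirical SDs, and mean/median
#' performance measures.  These are the "true" values the missing-data
#' methods are evaluated against.
#'
#' @param config A [study_config()].
#' @param population Optional pre-generated population (regenerated
#'   from `config$population` otherwise).
#' @return Object of class `true_values`.
#' @export
run_truth <- function(config = study_config(), population = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (config$truth_replications < 2) {
    stop("at least 2 truth replications are required to estimate se_true")
  }
  if (is.null(population)) {
    pop_cfg <- config$population
    pop_cfg$seed <- derive_seed(config$seed, "population")
    population <- generate_population(pop_cfg)
  }
  covs <- covariate_names()
  betas <- matrix(NA_real_, config$truth_replications, length(covs),
                  dimnames = list(NULL, covs))
  perf <- matrix(NA_real_, config$truth_replications,
                 2 + length(config$pred_times))
  for (i in seq_len(config$truth_replications)) {
    set.seed(derive_seed(config$seed, "truth", i))
    smp <- draw_bootstrap_sample(population, config$n_sample)
    mm <- fit_and_measure(smp, config$pred_times)
    if (!is.null(mm$fit) && mm$fit$converged) {
      betas[i, ] <- mm$fit$beta
      perf[i, ] <- c(mm$r2, mm$d, mm$surv)
    }
  }
  ok <- stats::complete.cases(betas)
  if (sum(ok) < 2) stop("fewer than 2 successful truth replications")
  surv_true <- colMeans(perf[ok, -(1:2), drop = FALSE], na.rm = TRUE)
  names(surv_true) <- paste0("surv", config$pred_times)
  structure(list(beta_true = colMeans(betas[ok, , drop = FALSE]),
                 se_true = apply(betas[ok, , drop = FALSE], 2, stats::sd),
                 r2_true = stats::median(perf[ok, 1], na.rm = TRUE),
                 d_true = mean(perf[ok, 2], na.rm = TRUE),
                 surv_true = surv_true,
                 n_replications = sum(ok),
                 n_failed = sum(!ok)),
            class = "true_values")
}

#' Run the full resampling study
#'
#' For each replication a bootstrap sample is drawn; for each
#' missingness rate the sample is amputed once (shared by all
#' methods); each method completes the data, the Cox model is fitted
#' to every completion, and results are pooled.  Failures (e.g.
#' complete-case non-convergence at high missingness) are recorded
#' with their context and the study continues.
#'
#' @param config A [study_config()].
#' @param truth Optional pre-computed `true_values`; computed from the
#'   config otherwise.
#' @return Object of class `study_result`: raw per-replication
#'   `coefficients` and `performance` tables, the evaluation `summary`
#'   (one row per method x p0 x covariate), the per-cell
#'   `performance_summary`, `truth`, `failures`, and the `config`.
#' @export
run_study <- function(config = study_config(), truth = NULL) {
  stopifnot(inherits(config, "study_config"))
  pop_cfg <- config$population
  pop_cfg$seed <- derive_seed(config$seed, "population")
  population <- generate_population(pop_cfg)
  if (is.null(truth)) truth <- run_truth(config, population = population)
  coef_rows <- list()
  perf_rows <- list()
  failures <- list()
  for (i in seq_len(config$n_replications)) {
    set.seed(derive_seed(config$seed, "sample", i))
    smp <- draw_bootstrap_sample(population, config$n_sample)
    for (pj in seq_along(config$p0_grid)) {
      p0 <- config$p0_grid[pj]
      amp_cfg <- amputation_config(p0, seed = derive_seed(config$seed,
                                                          "ampute", i, pj))
      incomplete <- impose_mar(smp, config = amp_cfg)
      for (mk in seq_along(config$methods)) {
        method <- config$methods[mk]
        imp_cfg <- imputation_config(
          engine = method, m = config$m, n_cycles = config$n_cycles,
          donor_pool_k = config$donor_pool_k,
          seed = derive_seed(config$seed, "impute", i, pj, mk))
        completions <- tryCatch(impute_missing(incomplete, imp_cfg),
                                error = function(e) e)
        if (inherits(completions, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(replication = i, p0 = p0, method = method,
                       stage = "imputation",
                       message = conditionMessage(completions))
          completions <- list()
        }
        measures <- lapply(completions, fit_and_measure, config$pred_times)
        for (mm in measures) {
          if (!is.null(mm$error) && !is.na(mm$error)) {
            failures[[length(failures) + 1L]] <-
              data.frame(replication = i, p0 = p0, method = method,
                         stage = "cox_fit", message = mm$error)
          }
        }
        pooled <- pool_method_results(measures, method, p0, i,
                                      config$pred_times)
        coef_rows[[length(coef_rows) + 1L]] <- pooled$coefficients
        perf_rows[[length(perf_rows) + 1L]] <- pooled$performance
      }
    }
  }
  coefficients <- do.call(rbind, coef_rows)
  performance <- do.call(rbind, perf_rows)
  summary <- evaluate(coefficients, truth)
  performance_summary <- summarise_performance(performance, config$pred_times)
  structure(list(coefficients = coefficients, performance = performance,
                 summary = summary,
                 performance_summary = performance_summary,
                 truth = truth,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = config),
            class = "study_result")
}

summarise_performance <- function(performance, pred_times) {
  cells <- unique(performance[, c("method", "p0")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- performance[performance$method == cells$method[i] &
                         performance$p0 == cells$p0[i], , drop = FALSE]
    ok <- sub[sub$converged, , drop = FALSE]
    out <- data.frame(cells[i, ],
                      n_used = nrow(ok), n_failed = nrow(sub) - nrow(ok),
                      r2_median = stats::median(ok$r2, na.rm = TRUE),
                      r2_iqr_lower = stats::median(ok$r2_iqr_lower,
                                                   na.rm = TRUE),
                      r2_iqr_upper = stats::median(ok$r2_iqr_upper,
                                                   na.rm = TRUE),
                      d_mean = mean(ok$d, na.rm = TRUE))
    for (t in pred_times) {
      cn <- paste0("surv", t)
      out[[paste0(cn, "_mean")]] <- mean(ok[[cn]], na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
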