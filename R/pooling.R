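# Rubin's rules for combining multiply imputed analyses, pooling of
# performance measures, and the bias/coverage/efficiency evaluation of
# methods against truth-run values.

#' Combine repeated estimates by Rubin's rules
#'
#' Pooled point estimate q_bar, within-imputation variance w_bar,
#' between-imputation variance b, total variance
#' t = w_bar + (1 + 1/m) b, Rubin degrees of freedom
#' (m - 1)(1 + w_bar / ((1 + 1/m) b))^2, and a 95% interval using the
#' t quantile on those df (normal quantile when m = 1 or b = 0).
#'
#' @param estimates Per-imputation point estimates (length m >= 1).
#' @param variances Per-imputation squared standard errors, positive.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `pooled_estimate`: `q_bar`, `w_bar`, `b`,
#'   `t_var`, `se`, `df`, `ci` (length 2), `p`, `m`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m, all(variances > 0))
  q_bar <- mean(estimates)
  w_bar <- mean(variances)
  if (m == 1) {
    b <- NA_real_
    t_var <- w_bar
    df <- Inf
  } else {
    b <- stats::var(estimates)
    t_var <- w_bar + (1 + 1 / m) * b
    df <- if (b == 0) Inf else (m - 1) * (1 + w_bar / ((1 + 1 / m) * b))^2
  }
  se <- sqrt(t_var)
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- q_bar / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  structure(list(q_bar = q_bar, w_bar = w_bar, b = b, t_var = t_var,
                 se = se, df = df, ci = c(q_bar - q * se, q_bar + q * se),
                 p = p, m = m),
            class = "pooled_estimate")
}

#' Pool a performance measure across imputations
#'
#' R-squared is pooled as the median (the interquartile range is
#' retained); the D statistic is averaged on its raw scale; predicted
#' survival probabilities are averaged on the complementary log-log
#' scale and back-transformed.
#'
#' @param values Per-imputation values of the measure.
#' @param kind `"r2"`, `"d"` or `"survival"`.
#' @return For `"r2"`, list with `value` (median) and `iqr`; otherwise
#'   a single pooled value.
#' @export
pool_performance <- function(values, kind = c("r2", "d", "survival")) {
  kind <- match.arg(kind)
  stopifnot(length(values) >= 1)
  switch(kind,
         r2 = list(value = stats::median(values),
                   iqr = unname(stats::quantile(values, c(0.25, 0.75)))),
         d = mean(values),
         survival = {
           stopifnot(all(values > 0), all(values < 1))
           exp(-exp(mean(log(-log(values)))))
         })
}

#' Replications needed to estimate a coefficient to a given accuracy
#'
#' ceil((1.96 se / (accuracy |beta|))^2): the number of replications
#' for which the Monte-Carlo standard error of the mean estimate is at
#' most `accuracy * |beta|` at the 95% level.
#'
#' @param beta Non-zero coefficient value.
#' @param se Its standard error, positive.
#' @param accuracy Relative accuracy in (0, 1), e.g. 0.05.
#' @return Integer number of replications.
#' @export
required_replications <- function(beta, se, accuracy = 0.05) {
  stopifnot(se > 0, accuracy > 0, accuracy < 1)
  if (beta == 0) {
    stop("accuracy-based replication counts are undefined for beta = 0")
  }
  as.integer(ceiling((1.96 * se / (accuracy * abs(beta)))^2))
}

#' Evaluate replication results against truth-run values
#'
#' For every method x missingness-rate x covariate cell: mean estimate,
#' bias, percent bias (absent when the true coefficient is zero),
#' empirical SE (SD of estimates), mean model SE, coverage of the
#' nominal 95% intervals, rejection rate at the 5% level, and a
#' `problematic` flag marking |bias| > 0.5 * se_true.  Failed
#' replications are tallied per cell and excluded from the summaries,
#' never silently dropped.
#'
#' @param results Data frame of per-replication coefficient rows with
#'   columns `method, p0, replication, covariate, estimate, se,
#'   ci_lower, ci_upper, p, converged`.
#' @param truth A `true_values` object from [run_truth()].
#' @return Data frame, one row per method x p0 x covariate.
#' @export
evaluate <- function(results, truth) {
  stopifnot(inherits(truth, "true_values"))
  cells <- unique(results[, c("method", "p0", "covariate")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- results[results$method == cell$method & results$p0 == cell$p0 &
                     results$covariate == cell$covariate, , drop = FALSE]
    ok <- sub[sub$converged & is.finite(sub$estimate) & is.finite(sub$se), ,
              drop = FALSE]
    n_fail <- nrow(sub) - nrow(ok)
    bt <- truth$beta_true[[cell$covariate]]
    st <- truth$se_true[[cell$covariate]]
    if (nrow(ok) < 2) {
      return(data.frame(cell, n_used = nrow(ok), n_failed = n_fail,
                        mean_estimate = NA_real_, bias = NA_real_,
                        pct_bias = NA_real_, empirical_se = NA_real_,
                        mean_model_se = NA_real_, coverage = NA_real_,
                        rejection_rate = NA_real_, problematic = NA))
    }
    bias <- mean(ok$estimate) - bt
    data.frame(cell, n_used = nrow(ok), n_failed = n_fail,
               mean_estimate = mean(ok$estimate),
               bias = bias,
               pct_bias = if (bt == 0) NA_real_ else 100 * bias / bt,
               empirical_se = stats::sd(ok$estimate),
               mean_model_se = mean(ok$se),
               coverage = mean(ok$ci_lower <= bt & bt <= ok$ci_upper),
               rejection_rate = mean(ok$p < 0.05),
               problematic = abs(bias) > 0.5 * st)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
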