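# Prognostic-model performance measures computed from a fitted Cox
# model: Nagelkerke pseudo R-squared, the Royston-Sauerbrei prognostic
# separation statistic D, and model-based predicted survival.

#' Nagelkerke pseudo R-squared of a Cox fit
#'
#' Cox-Snell R2 = 1 - exp(-(2/n)(l1 - l0)) rescaled by its maximum
#' 1 - exp((2/n) l0).  `n` is the total sample size by default; the
#' event-count variant is available via `n_type = "events"`.
#'
#' @param fit A `cox_fit`.
#' @param n_type `"cases"` (default) or `"events"`.
#' @return R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit, n_type = c("cases", "events")) {
  n_type <- match.arg(n_type)
  n <- if (n_type == "cases") fit$n else fit$n_events
  l0 <- fit$loglik_null
  l1 <- fit$loglik_fit
  if (l0 == 0) stop("null log-likelihood is zero (no events?)")
  r2_cs <- 1 - exp(-(2 / n) * (l1 - l0))
  r2_max <- 1 - exp((2 / n) * l0)
  r2_cs / r2_max
}

#' Royston-Sauerbrei prognostic separation statistic D
#'
#' Ranks the linear predictor (average ranks on ties), maps ranks to
#' expected normal order scores by the Blom approximation
#' qnorm((r - 3/8)/(n + 1/4)), scales by kappa = sqrt(8/pi), and
#' returns the coefficient of a univariate Cox model on the scaled
#' score.  A constant predictor yields D = 0 by convention.
#'
#' @param linear_predictor Per-case prognostic index.
#' @param time,event Outcome vectors.
#' @param ties Tie handling for the internal Cox fit.
#' @return The D statistic (log hazard ratio per prognostic-index
#'   standard-normal unit).
#' @export
royston_d <- function(linear_predictor, time, event, ties = "efron") {
  n <- length(linear_predictor)
  stopifnot(n >= 3, length(time) == n, length(event) == n, sum(event) >= 1)
  if (stats::sd(linear_predictor) == 0) return(0)
  r <- rank(linear_predictor, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
  df <- data.frame(z = z, time = time, event = event)
  fit <- fit_cox(df, covariates = "z", ties = ties, tol = 1e-12)
  unname(fit$beta)
}

#' Model-based predicted survival probability at a time point
#'
#' Breslow baseline cumulative hazard at the fitted coefficients with
#' the linear predictor centred at its training mean; the reported
#' probability is the average over cases of the individual predicted
#' curves exp(-H0(t) * exp(PI_i - mean(PI))).
#'
#' @param fit A `cox_fit`.
#' @param newdata Optional dataset for which to predict; defaults to
#'   the training data's linear predictor.
#' @param t Prediction time in years; must not exceed the largest
#'   observed training time.
#' @return Mean predicted survival probability at `t`.
#' @export
predicted_survival <- function(fit, newdata = NULL, t) {
  stopifnot(t >= 0)
  if (t > max(fit$time)) {
    stop("prediction time ", t, " beyond last observed time ",
         signif(max(fit$time), 4))
  }
  if (t == 0) return(1)
  H0 <- breslow_cumhaz(fit, t)
  lp_bar <- mean(fit$linear_predictor)
  lp <- if (is.null(newdata)) {
    fit$linear_predictor
  } else {
    drop(as.matrix(newdata[, names(fit$beta), drop = FALSE]) %*% fit$beta)
  }
  mean(exp(-H0 * exp(lp - lp_bar)))
}
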