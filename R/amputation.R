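# Multivariate MAR amputation of stage, post_rt and age following a
# fixed seven-pattern table with case selection driven by a logistic
# missingness score.

amputable_columns <- function() c("stage", "post_rt", "age")

#' The packaged seven-pattern missingness table
#'
#' Patterns over (stage, post_rt, age) with 1 = observed, 0 = missing,
#' and their assignment probabilities, taken from an ovarian cancer
#' study's observed missingness: stage is missing in 71% of incomplete
#' cases, post-operative RT in 63% and age in 24% (as implied by the
#' probabilities), and the expected number of missing items per
#' incomplete case is 1.58.
#'
#' @return Object of class `pattern_table`: list with `patterns`
#'   (7x3 0/1 matrix) and `p` (frequencies summing to 1).
#' @export
default_pattern_table <- function() {
  patterns <- matrix(c(
    1, 1, 0,
    1, 0, 1,
    1, 0, 0,
    0, 1, 1,
    0, 1, 0,
    0, 0, 1,
    0, 0, 0), ncol = 3, byrow = TRUE,
    dimnames = list(paste0("R", 1:7), amputable_columns()))
  pattern_table(patterns, c(0.08, 0.17, 0.04, 0.25, 0.04, 0.34, 0.08))
}

#' Construct and validate a pattern table
#'
#' @param patterns 0/1 matrix, one row per pattern, columns
#'   `stage, post_rt, age`; 0 marks a missing entry.  No row may be
#'   all-observed.
#' @param p Pattern frequencies; must sum to 1.
#' @return Object of class `pattern_table`.
#' @export
pattern_table <- function(patterns, p) {
  patterns <- as.matrix(patterns)
  stopifnot(ncol(patterns) == 3, nrow(patterns) == length(p),
            all(patterns %in% c(0, 1)), all(p >= 0),
            abs(sum(p) - 1) < 1e-12)
  if (any(rowSums(patterns) == 3)) {
    stop("a pattern with every entry observed cannot carry missingness")
  }
  colnames(patterns) <- amputable_columns()
  structure(list(patterns = patterns, p = p), class = "pattern_table")
}

#' Expected fraction of missing items per incomplete case
#'
#' Sum over patterns of p_i times the number of masked entries; 1.58
#' for the packaged table.
#'
#' @param patterns A `pattern_table`.
#' @return Expected count of missing items among the three amputable
#'   covariates for one incomplete case.
#' @export
expected_missing_items <- function(patterns = default_pattern_table()) {
  sum(patterns$p * rowSums(1 - patterns$patterns))
}

#' Configuration of the MAR amputation mechanism
#'
#' The missingness score is a weighted sum of standardised features:
#' shorter survival (via -log time), rectal/both-site cancer, a clear
#' chemotherapy indication, Dukes' C stage, planned post-operative RT,
#' and older age.  With the default unit weights, incomplete cases are
#' on average older, shorter-surviving, more often Dukes' C and more
#' often planned for post-operative RT.
#'
#' @param p0 Overall fraction of incomplete cases, in (0,1); the study
#'   grid is 0.05, 0.10, 0.25, 0.50, 0.75.
#' @param mar_weights Named weights on the score features
#'   `minus_log_time, site, ct_indic_clear, stage, post_rt, age`.
#' @param seed Optional integer seed consumed by [impose_mar()].
#' @return Object of class `amputation_config`.
#' @export
amputation_config <- function(p0,
                              mar_weights = c(minus_log_time = 1, site = 1,
                                              ct_indic_clear = 1, stage = 1,
                                              post_rt = 1, age = 1),
                              seed = NULL) {
  stopifnot(length(p0) == 1, p0 > 0, p0 < 1,
            setequal(names(mar_weights),
                     c("minus_log_time", "site", "ct_indic_clear", "stage",
                       "post_rt", "age")))
  structure(list(p0 = p0, mar_weights = mar_weights, seed = seed),
            class = "amputation_config")
}

mar_score <- function(data, weights) {
  feats <- cbind(minus_log_time = -log(data$time),
                 site = data$site,
                 ct_indic_clear = 1 - data$ct_indic,
                 stage = data$stage,
                 post_rt = data$post_rt,
                 age = data$age)
  sds <- apply(feats, 2, stats::sd)
  sds[sds == 0] <- 1
  feats <- scale(feats, center = TRUE, scale = sds)
  drop(feats %*% weights[colnames(feats)])
}

#' Impose multivariate MAR missingness
#'
#' Selects exactly `round(p0 * n)` cases to be incomplete by weighted
#' sampling without replacement with weights `plogis(score)`, where the
#' score is the standardised MAR score of [amputation_config()].  Each
#' selected case is independently assigned one of the seven patterns
#' with the table's probabilities, and the masked entries of stage,
#' post_rt and age are set to `NA`.  Outcome columns are never masked.
#'
#' @param data Complete dataset (no missing values).
#' @param patterns A `pattern_table`; default the packaged table.
#' @param config An [amputation_config()].
#' @return The dataset with `NA`s in the masked cells (an incomplete
#'   dataset); the missingness mask is `is.na()` on the three amputable
#'   columns.
#' @export
impose_mar <- function(data, patterns = default_pattern_table(), config) {
  stopifnot(inherits(patterns, "pattern_table"),
            inherits(config, "amputation_config"),
            !anyNA(data))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(data)
  n_incomplete <- round(config$p0 * n)
  if (n_incomplete < 1) {
    stop("p0 * n rounds to zero incomplete cases; increase p0 or n")
  }
  score <- mar_score(data, config$mar_weights)
  w <- stats::plogis(score)
  if (stats::sd(w) < .Machine$double.eps^0.5) {
    warning("degenerate MAR score; falling back to uniform selection")
    w <- rep(1, n)
  }
  sel <- sample.int(n, n_incomplete, replace = FALSE, prob = w)
  pat_idx <- sample.int(nrow(patterns$patterns), n_incomplete,
                        replace = TRUE, prob = patterns$p)
  out <- data
  for (j in seq_along(amputable_columns())) {
    col <- amputable_columns()[j]
    mask_rows <- sel[patterns$patterns[pat_idx, j] == 0]
    out[mask_rows, col] <- NA
  }
  out
}

#' Summarise realized missingness
#'
#' @param data An incomplete dataset as returned by [impose_mar()].
#' @return List with the realized incomplete-case fraction `p0`,
#'   realized pattern frequencies among incomplete cases, the
#'   percentage of covariate items still observed (out of 8 per case),
#'   per-covariate missing percentages (of all cases and of incomplete
#'   cases), and MAR diagnostics comparing complete and incomplete
#'   cases on age and follow-up time.
#' @export
missingness_summary <- function(data) {
  n <- nrow(data)
  mask <- is.na(data[, amputable_columns(), drop = FALSE])
  incomplete <- rowSums(mask) > 0
  n_inc <- sum(incomplete)
  pat_lab <- apply(1 - mask[incomplete, , drop = FALSE], 1, paste,
                   collapse = "")
  pat_freq <- if (n_inc > 0) table(pat_lab) / n_inc else table(character(0))
  items_total <- n * length(covariate_names())
  pct_available <- 100 * (items_total - sum(mask)) / items_total
  per_cov_all <- 100 * colMeans(mask)
  per_cov_inc <- if (n_inc > 0) 100 * colSums(mask) / n_inc else per_cov_all * NA
  diag <- list(
    mean_age_complete = mean(data$age[!incomplete], na.rm = TRUE),
    mean_age_incomplete = if (n_inc > 0)
      mean(data$age[incomplete], na.rm = TRUE) else NA_real_,
    median_time_complete = stats::median(data$time[!incomplete]),
    median_time_incomplete = if (n_inc > 0)
      stats::median(data$time[incomplete]) else NA_real_)
  list(p0 = n_inc / n,
       n_incomplete = n_inc,
       pattern_frequencies = pat_freq,
       pct_items_available = pct_available,
       pct_missing_by_covariate = per_cov_all,
       pct_missing_of_incomplete = per_cov_inc,
       mar_diagnostics = diag)
}
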