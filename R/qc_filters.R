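#' @name qc_filters
#' @title Respondent-level quality filters
#'
#' @description
#' Two sequential exclusion rules are applied before modelling.  First,
#' respondents who completed fewer than 10 TTO tasks are dropped (too
#' little information to judge response quality).  Second, respondents
#' whose TTO values *increase* with the misery index of the states --
#' i.e. who value worse states higher, an ordinary least-squares slope
#' strictly greater than zero -- are dropped as inconsistent responders.
#' The rules are applied in that order and each respondent is counted
#' under at most one rule, so the audit arithmetic
#' `n_retained = n_input - n_min_obs - n_positive_slope` always holds.
NULL

#' OLS slope of a respondent's TTO values on the misery index
#'
#' @param values Numeric vector of TTO values.
#' @param misery Integer vector of misery indices (same length).
#' @return The least-squares slope, or `NA` when fewer than 2
#'   observations or no variation in misery (slope undefined).
#' @export
respondent_slope <- function(values, misery) {
  stopifnot(length(values) == length(misery))
  if (length(values) < 2L) return(NA_real_)
  mx <- mean(misery)
  sxx <- sum((misery - mx)^2)
  if (sxx < 1e-12) return(NA_real_)
  sum((misery - mx) * (values - mean(values))) / sxx
}

#' Exclude respondents with fewer than a minimum number of observations
#'
#' @param data A [tto_data] object.
#' @param min_obs Minimum task count; the default 10 keeps respondents
#'   with exactly 10 observations ("fewer than 10" excludes 9 or fewer).
#' @return List with `data` (kept dataset) and `excluded` (character
#'   vector of dropped respondent ids).
#' @export
filter_min_observations <- function(data, min_obs = 10L) {
  stopifnot(inherits(data, "tto_data"))
  counts <- table(data$respondent_id)
  drop <- names(counts)[counts < min_obs]
  list(data = subset_tto(data, !(data$respondent_id %in% drop)),
       excluded = drop)
}

#' Exclude respondents with a positively sloped value-misery relationship
#'
#' Respondents whose OLS slope of TTO value on misery index is strictly
#' positive (beyond 1e-12) are excluded; a slope of exactly zero is not
#' positive and is retained.  Respondents with an undefined slope (no
#' variation in misery across their tasks) are retained with a warning:
#' an undefined slope is no evidence of inconsistent responding.
#'
#' @param data A [tto_data] object (normally already past
#'   [filter_min_observations()]).
#' @return List with `data`, `excluded`, and `slopes` (named vector of
#'   per-respondent slopes).
#' @export
filter_positive_slope <- function(data) {
  stopifnot(inherits(data, "tto_data"))
  mis <- misery_index(data$state)
  ids <- unique(data$respondent_id)
  slopes <- vapply(ids, function(id) {
    sel <- data$respondent_id == id
    respondent_slope(data$value[sel], mis[sel])
  }, numeric(1))
  names(slopes) <- ids
  if (anyNA(slopes)) {
    warning(sum(is.na(slopes)),
            " respondent(s) with undefined value-misery slope retained",
            call. = FALSE)
  }
  drop <- ids[!is.na(slopes) & slopes > 1e-12]
  list(data = subset_tto(data, !(data$respondent_id %in% drop)),
       excluded = drop, slopes = slopes)
}

#' Run both quality filters with an audit trail
#'
#' @param data A [tto_data] object.
#' @param min_obs Passed to [filter_min_observations()].
#' @return List with `data` (kept dataset) and `report`, a `qc_report`
#'   holding the input/excluded/retained counts and the per-respondent
#'   decisions (id, rule, statistic).
#' @export
run_qc <- function(data, min_obs = 10L) {
  stopifnot(inherits(data, "tto_data"))
  n_input <- n_respondents(data)
  s1 <- filter_min_observations(data, min_obs = min_obs)
  s2 <- filter_positive_slope(s1$data)
  counts <- table(data$respondent_id)
  decisions <- rbind(
    if (length(s1$excluded)) {
      data.frame(respondent_id = s1$excluded, rule = "min_obs",
                 statistic = as.numeric(counts[s1$excluded]))
    },
    if (length(s2$excluded)) {
      data.frame(respondent_id = s2$excluded, rule = "positive_slope",
                 statistic = as.numeric(s2$slopes[s2$excluded]))
    })
  if (is.null(decisions)) {
    decisions <- data.frame(respondent_id = character(),
                            rule = character(), statistic = numeric())
  }
  report <- structure(list(
    n_input = n_input,
    n_excluded_min_obs = length(s1$excluded),
    n_excluded_positive_slope = length(s2$excluded),
    n_retained = n_respondents(s2$data),
    decisions = decisions,
    min_obs = min_obs), class = "qc_report")
  stopifnot(report$n_retained ==
              report$n_input - report$n_excluded_min_obs -
              report$n_excluded_positive_slope)
  list(data = s2$data, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Respondent QC report\n")
  cat(sprintf("  input respondents:            %d\n", x$n_input))
  cat(sprintf("  excluded, < %d observations:  %d\n",
              x$min_obs, x$n_excluded_min_obs))
  cat(sprintf("  excluded, positive slope:     %d\n",
              x$n_excluded_positive_slope))
  cat(sprintf("  retained:                     %d\n", x$n_retained))
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}

qc_report_to_list <- function(x) {
  list(n_input = x$n_input,
       n_excluded_min_obs = x$n_excluded_min_obs,
       n_excluded_positive_slope = x$n_excluded_positive_slope,
       n_retained = x$n_retained,
       min_obs = x$min_obs,
       decisions = x$decisions)
}
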