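#' @name valueset_monitor
#' @title Demographically weighted value sets and their difference
#'
#' @description
#' A value set assigns each EQ-5D-3L state a societal value built from
#' ten dimension-level decrements.  With demographic scale parameters,
#' the population-level decrement for dimension `d`, level `l` under a
#' demographic composition `w` is the weighted average
#' \deqn{\beta_{dl} \sum_c w_c\, \varphi_{d,c},}
#' i.e. the average decrement weighted by the population share of each
#' sex x age cell.  Computing this per posterior draw under two
#' compositions ("original" at the time of data collection, "updated"
#' for a later year) gives the posterior distribution of each decrement
#' under both weightings and of their difference, reported here as
#' `updated - original`.  A negative difference means the decrement grew
#' in magnitude (decrements are negative); Table-style reports print the
#' raw signed difference.
NULL

#' Population-weighted decrement
#'
#' @param beta_dl Decrement coefficient for one dimension-level.
#' @param phi_d Named vector of that dimension's scale parameters over
#'   the cells.
#' @param weights A [demographic_weights] object (or named vector
#'   summing to 1) covering all cells of `phi_d`.
#' @return `beta_dl * sum(w_c * phi_d[c])`.
#' @export
weighted_decrement <- function(beta_dl, phi_d, weights) {
  miss <- setdiff(names(phi_d), names(weights))
  if (length(miss)) {
    stop("weights missing cell(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(weights[names(phi_d)])
  beta_dl * sum(w * as.numeric(phi_d))
}

draws_matrix_of <- function(draws) {
  if (inherits(draws, "tobit_fit")) return(as.matrix(draws))
  if (is.list(draws) && !is.data.frame(draws)) return(do.call(rbind, draws))
  as.matrix(draws)
}

#' Compute value-set draws under two demographic weightings
#'
#' For every retained posterior draw, the ten weighted decrements are
#' computed under `weights_original` and `weights_updated`, together
#' with their difference (`updated - original`, exact per draw).
#' Computing this after sampling on the stored draws is algebraically
#' identical to monitoring it inside the sampler; the stored-draw path
#' is canonical because it decouples fitting from weighting.
#'
#' @param draws A `tobit_fit`, a list of per-chain draw matrices, or one
#'   stacked draw matrix with the fit's parameter names.
#' @param weights_original,weights_updated [demographic_weights] objects
#'   covering all model cells.
#' @return Object of class `valueset_draws`: matrices `original`,
#'   `updated`, `diff` (draws x 10 decrements) plus weighting labels.
#' @export
monitor_valuesets <- function(draws, weights_original, weights_updated) {
  m <- draws_matrix_of(draws)
  cells <- if (inherits(draws, "tobit_fit")) draws$cells else {
    nm <- grep("^phi_MO\\[", colnames(m), value = TRUE)
    sub("^phi_MO\\[(.*)\\]$", "\\1", nm)
  }
  if (!length(cells)) stop("no scale-parameter columns found", call. = FALSE)
  for (w in list(weights_original, weights_updated)) {
    miss <- setdiff(cells, names(w))
    if (length(miss)) {
      stop("weights missing cell(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  wo <- as.numeric(weights_original[cells])
  wu <- as.numeric(weights_updated[cells])
  labs <- decrement_labels()
  n <- nrow(m)
  orig <- upd <- matrix(NA_real_, n, 10L, dimnames = list(NULL, labs))
  for (d in seq_len(5L)) {
    phi_cols <- paste0("phi_", eq5d_dimensions[d], "[", cells, "]")
    ph <- m[, phi_cols, drop = FALSE]
    mean_o <- as.vector(ph %*% wo)
    mean_u <- as.vector(ph %*% wu)
    for (l in 1:2) {
      j <- 2L * (d - 1L) + l
      b <- m[, labs[j]]
      orig[, j] <- b * mean_o
      upd[, j] <- b * mean_u
    }
  }
  structure(list(original = orig, updated = upd, diff = upd - orig,
                 label_original = attr(weights_original, "label"),
                 label_updated = attr(weights_updated, "label")),
            class = "valueset_draws")
}

#' @export
print.valueset_draws <- function(x, ...) {
  cat(sprintf("Value-set draws: %d draws x 10 decrements (%s vs %s)\n",
              nrow(x$original),
              x$label_original %||% "original",
              x$label_updated %||% "updated"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior summary of value-set draws
#'
#' Equal-tailed credible intervals from percentile order statistics with
#' linear interpolation (quantile type 7), so summaries are reproducible
#' across runs and invariant to draw order.  A difference is flagged
#' significant when its interval excludes 0.
#'
#' @param vs_draws A [monitor_valuesets()] result.
#' @param level Credible level (default 0.95).
#' @return Data frame with one row per decrement label: mean, lower and
#'   upper bound for original, updated and difference, plus a
#'   `significant` flag for the difference.
#' @export
summarize_valuesets <- function(vs_draws, level = 0.95) {
  stopifnot(inherits(vs_draws, "valueset_draws"), level > 0, level < 1)
  n <- nrow(vs_draws$original)
  if (n < 2 / (1 - level)) {
    stop("too few draws (", n, ") for ", level * 100,
         "% credible intervals", call. = FALSE)
  }
  a <- (1 - level) / 2
  qs <- function(m, p) apply(m, 2L, quantile, probs = p, type = 7,
                             names = FALSE)
  out <- data.frame(
    label = decrement_labels(),
    original_mean = colMeans(vs_draws$original),
    original_lo = qs(vs_draws$original, a),
    original_hi = qs(vs_draws$original, 1 - a),
    updated_mean = colMeans(vs_draws$updated),
    updated_lo = qs(vs_draws$updated, a),
    updated_hi = qs(vs_draws$updated, 1 - a),
    diff_mean = colMeans(vs_draws$diff),
    diff_lo = qs(vs_draws$diff, a),
    diff_hi = qs(vs_draws$diff, 1 - a),
    row.names = NULL)
  out$significant <- out$diff_lo > 0 | out$diff_hi < 0
  out
}

#' @export
summary.valueset_draws <- function(object, level = 0.95, ...) {
  summarize_valuesets(object, level = level)
}

#' Predict the value of a health state
#'
#' Applies a fitted preference structure to EQ-5D-3L profiles: the
#' predicted value is the intercept plus the weighted decrements selected
#' by the state's dummies.
#'
#' @param x A [model_params] object (single draw; requires `weights`) or
#'   a value-set summary data frame from [summarize_valuesets()].
#' @param state Character vector of state codes.
#' @param weights [demographic_weights], required for `model_params`
#'   input.
#' @param which For summary input, `"original"` or `"updated"` column
#'   block.
#' @param intercept For summary input, the value of full health
#'   (`"11111"`); summaries carry decrements only.
#' @return Numeric vector of predicted values.
#' @export
predict_state_value <- function(x, state, weights = NULL,
                                which = c("updated", "original"),
                                intercept = 1) {
  which <- match.arg(which)
  X <- encode_state(state)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, decrement_labels()))
  if (inherits(x, "model_params")) {
    if (is.null(weights)) {
      stop("weights are required to aggregate scale parameters",
           call. = FALSE)
    }
    dec <- vapply(seq_len(10L), function(j) {
      d <- (j + 1L) %/% 2L
      weighted_decrement(x$beta[j], x$phi[d, ], weights)
    }, numeric(1))
    return(as.vector(x$beta0 + X %*% dec))
  }
  x <- as.data.frame(x)
  stopifnot(all(c("label", paste0(which, "_mean")) %in% names(x)))
  dec <- x[[paste0(which, "_mean")]][match(decrement_labels(), x$label)]
  as.vector(intercept + X %*% dec)
}
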