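#' @name synthetic_data
#' @title Synthetic TTO valuation studies
#'
#' @description
#' Generates valuation datasets with the statistical structure the
#' analysis assumes -- latent normal values with state-severity-dependent
#' noise, demographic scale parameters, censoring at -1 -- plus planted
#' contaminant respondents for testing the quality filters: low
#' completers (fewer than 10 tasks) and positive-slope responders (values
#' generated with sign-flipped decrements, which guarantees a positive
#' expected value-misery slope).
#'
#' Two design dialects are emulated: `"fixed-17"`, where every respondent
#' values the same 17 states, and `"sampled-12-of-45"`, where each
#' respondent values a simple random sample of 12 distinct states from a
#' 45-state design.  The original studies' exact design state lists are
#' not reproduced here; the pools are documented synthetic stand-ins
#' with matched cardinalities, spanning misery indices 6 to 15 and
#' including the worst state `"33333"`.  Users with the real designs can
#' inject them via the `pool` argument of [make_design()].
NULL

#' Synthetic stand-in design pools
#'
#' `design_pool_45()` deterministically selects 45 states stratified by
#' misery index (all misery-6 and misery-14 states, `"33333"`, and
#' evenly spaced states in between); `design_fixed_17()` is an evenly
#' spaced 17-state subset of it, mildest to worst.
#'
#' @return Character vector of state codes.
#' @export
design_pool_45 <- function() {
  states <- all_eq5d_states()
  mis <- misery_index(states)
  alloc <- c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L, 5L, 1L)  # misery 6..15
  pool <- unlist(lapply(seq_along(alloc), function(i) {
    s <- states[mis == i + 5L]
    s[round(seq(1L, length(s), length.out = alloc[i]))]
  }))
  unname(pool)
}

#' @rdname design_pool_45
#' @export
design_fixed_17 <- function() {
  pool <- design_pool_45()
  pool[round(seq(1L, length(pool), length.out = 17L))]
}

#' Default data-generating truths styled on the three source studies
#'
#' Returns a complete truth scenario for a given country style: true
#' decrements set at the country's published value-set decrements, an
#' intercept near 1, mild heteroskedasticity (latent SD ranging from
#' about 0.2 at full health to about 0.5 for severe states), scale
#' parameters varying up to +/-25 percent across the 8 demographic
#' cells with exact mean 1 per dimension, the national demographic
#' composition of the study year, the study's design dialect, sample
#' size, and contamination rates matching the study's reported exclusion
#' counts.
#'
#' @param country_style `"UK"`, `"JPN"` or `"US"`.
#' @return Object of class `truth_scenario` with elements `params`
#'   ([model_params]), `composition` ([demographic_weights]), `dialect`,
#'   `n_respondents`, `n_tasks`, `low_completer_frac`,
#'   `positive_slope_frac`, `seed`.
#' @export
default_truth <- function(country_style = c("UK", "JPN", "US")) {
  country_style <- match.arg(country_style)
  beta <- switch(country_style,
    UK  = c(-0.06, -0.34, -0.11, -0.23, -0.08, -0.22, -0.09, -0.47,
            -0.12, -0.37),
    JPN = c(-0.10, -0.43, -0.05, -0.09, -0.03, -0.13, -0.06, -0.18,
            -0.06, -0.12),
    US  = c(-0.04, -0.34, -0.07, -0.24, -0.04, -0.17, -0.05, -0.36,
            -0.08, -0.26))
  comp <- switch(country_style,
                 UK = eq_weights("UK-1997"),
                 JPN = eq_weights("JPN-1998"),
                 US = eq_weights("US-2002"))
  size <- switch(country_style,
                 UK  = list(n = 3395L, low = 82 / 3395, slope = 43 / 3395),
                 JPN = list(n = 543L, low = 3 / 543, slope = 4 / 543),
                 US  = list(n = 4048L, low = 0, slope = 133 / 4048))
  dialect <- if (country_style == "JPN") "fixed-17" else "sampled-12-of-45"
  truth_scenario(
    params = model_params(beta0 = 0.95, beta = beta,
                          gamma = c(-1.0, -0.61, 0.05, 0, 0),
                          phi = default_phi(names(comp))),
    composition = comp, dialect = dialect,
    n_respondents = size$n, n_tasks = if (dialect == "fixed-17") 17L else 12L,
    low_completer_frac = size$low, positive_slope_frac = size$slope)
}

# scale-parameter pattern: a smooth age trend plus a sex contrast per
# dimension, mean-zero contrasts so each row averages exactly 1
default_phi <- function(cells) {
  stopifnot(length(cells) == 8L)
  age <- rep(c(-1, -1 / 3, 1 / 3, 1), times = 2L)
  sex <- rep(c(-1, 1), each = 4L)
  amp <- rbind(MO = c(0.20, 0.00), SC = c(0.10, 0.05), UA = c(-0.15, 0.05),
               PD = c(0.05, -0.15), AD = c(-0.10, 0.10))
  phi <- 1 + outer(amp[, 1], age) + outer(amp[, 2], sex)
  dimnames(phi) <- list(eq5d_dimensions, cells)
  phi
}

#' Construct a truth scenario
#'
#' @param params True [model_params].
#' @param composition [demographic_weights] used to sample respondents'
#'   demographic cells.
#' @param dialect `"fixed-17"` or `"sampled-12-of-45"`.
#' @param n_respondents Number of respondents (contaminants included).
#' @param n_tasks Tasks per clean respondent.
#' @param low_completer_frac,positive_slope_frac Contamination rates in
#'   `[0, 1)`.
#' @param seed Default seed used by [simulate_study()].
#' @return Object of class `truth_scenario`.
#' @export
truth_scenario <- function(params, composition,
                           dialect = c("sampled-12-of-45", "fixed-17"),
                           n_respondents = 1000L, n_tasks = NULL,
                           low_completer_frac = 0,
                           positive_slope_frac = 0, seed = 1L) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(params, "model_params"),
            low_completer_frac >= 0, low_completer_frac < 1,
            positive_slope_frac >= 0, positive_slope_frac < 1,
            n_respondents >= 1)
  composition <- demographic_weights(composition,
                                     label = attr(composition, "label")
                                     %||% "composition")
  miss <- setdiff(params$cells, names(composition))
  if (length(miss)) {
    stop("composition missing cell(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(n_tasks)) n_tasks <- if (dialect == "fixed-17") 17L else 12L
  structure(list(params = params, composition = composition,
                 dialect = dialect, n_respondents = as.integer(n_respondents),
                 n_tasks = as.integer(n_tasks),
                 low_completer_frac = low_completer_frac,
                 positive_slope_frac = positive_slope_frac,
                 seed = as.integer(seed)),
            class = "truth_scenario")
}

#' Per-respondent task lists for a design dialect
#'
#' @param dialect `"fixed-17"` (everyone values the same list) or
#'   `"sampled-12-of-45"` (per-respondent simple random sample of
#'   `n_tasks` distinct states from the pool).
#' @param n_respondents Number of task lists to produce.
#' @param n_tasks Tasks per respondent.
#' @param pool State pool; defaults to the dialect's bundled stand-in
#'   pool.  Supply the real design here if available.
#' @return List of character vectors of state codes, one per respondent.
#'   Uses the current RNG state; seed upstream for determinism.
#' @export
make_design <- function(dialect = c("sampled-12-of-45", "fixed-17"),
                        n_respondents, n_tasks = NULL, pool = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fixed-17") {
    if (is.null(pool)) pool <- design_fixed_17()
    if (is.null(n_tasks)) n_tasks <- length(pool)
    stopifnot(n_tasks == length(pool))
    rep(list(pool), n_respondents)
  } else {
    if (is.null(pool)) pool <- design_pool_45()
    if (is.null(n_tasks)) n_tasks <- 12L
    stopifnot(n_tasks <= length(pool))
    lapply(seq_len(n_respondents), function(i) sample(pool, n_tasks))
  }
}

#' Simulate a TTO valuation study from a truth scenario
#'
#' Respondents' demographic cells are drawn i.i.d. from the scenario's
#' composition; per task, a latent value is drawn from
#' `Normal(mu, sigma)` with `mu` and `sigma` given by the true model for
#' that state and cell, and censored to -1 when at or below -1.  Planted
#' contaminants: low completers receive 3 to 9 tasks; positive-slope
#' responders have their values generated with sign-flipped decrements.
#'
#' @param truth A [truth_scenario].
#' @param seed Seed for all randomness (defaults to the scenario's).
#' @return A [tto_data] object with attributes `planted_low` and
#'   `planted_slope` (the contaminant respondent ids) and `truth` (the
#'   scenario), the sidecar for recovery tests.
#' @export
simulate_study <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_scenario"))
  set.seed(seed)
  n <- truth$n_respondents
  n_low <- round(truth$low_completer_frac * n)
  n_slope <- round(truth$positive_slope_frac * n)
  stopifnot(n_low + n_slope <= n)
  ids <- sprintf("R%05d", seq_len(n))
  kind <- rep("clean", n)
  if (n_low + n_slope > 0) {
    contam <- sample(n, n_low + n_slope)
    kind[contam[seq_len(n_low)]] <- "low"
    if (n_slope > 0) kind[contam[n_low + seq_len(n_slope)]] <- "slope"
  }
  cells <- names(truth$composition)
  cell_of <- sample(cells, n, replace = TRUE,
                    prob = as.numeric(truth$composition))
  dialect <- if (truth$dialect == "fixed-17") "fixed-17" else "sampled-12-of-45"
  designs <- make_design(dialect, n, n_tasks = truth$n_tasks)
  # low completers: keep a random subset of 3..9 tasks
  for (i in which(kind == "low")) {
    k <- sample(3:9, 1L)
    designs[[i]] <- sample(designs[[i]], k)
  }
  n_obs <- lengths(designs)
  obs <- data.frame(
    respondent_id = rep(ids, n_obs),
    cell = rep(cell_of, n_obs),
    state = unlist(designs),
    kind = rep(kind, n_obs),
    stringsAsFactors = FALSE)
  X <- encode_state(obs$state)
  cell_idx <- match(obs$cell, truth$params$cells)
  mu <- latent_means(truth$params, X, cell_idx)
  flip <- obs$kind == "slope"
  if (any(flip)) {
    flipped <- truth$params
    flipped$beta <- -flipped$beta
    mu[flip] <- latent_means(flipped, X[flip, , drop = FALSE],
                             cell_idx[flip])
  }
  sigma <- scale_sd(truth$params, mu)
  latent <- rnorm(nrow(obs), mu, sigma)
  value <- ifelse(latent <= -1, -1, latent)
  parts <- strsplit(obs$cell, " ", fixed = TRUE)
  df <- data.frame(
    respondent_id = obs$respondent_id,
    sex = vapply(parts, `[[`, "", 1L),
    age_group = vapply(parts, `[[`, "", 2L),
    state = obs$state,
    value = value,
    stringsAsFactors = FALSE)
  out <- tto_data(df,
                  dialect = if (dialect == "fixed-17") "fixed" else "sampled",
                  provenance = sprintf("synthetic (%s, seed %d)",
                                       truth$dialect, seed))
  attr(out, "planted_low") <- ids[kind == "low"]
  attr(out, "planted_slope") <- ids[kind == "slope"]
  attr(out, "truth") <- truth
  out
}

#' Fraction of censored observations
#'
#' @param data A [tto_data] object.
#' @return Fraction of observations with value exactly -1; `NA` with a
#'   warning for an empty dataset (undefined).
#' @export
censoring_rate <- function(data) {
  stopifnot(inherits(data, "tto_data"))
  if (nrow(data) == 0L) {
    warning("censoring rate undefined for an empty dataset", call. = FALSE)
    return(NA_real_)
  }
  mean(data$value == -1)
}
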