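#' @name tobit_model
#' @title Heteroskedastic Tobit likelihood with demographic scale parameters
#'
#' @description
#' Observed TTO values are modelled as a censored version of a latent
#' normal variable: values at or below -1 are recorded as exactly -1 (the
#' censoring mass point), values above -1 are observed directly.  The
#' latent mean for an observation is
#'
#' \deqn{\mu = \beta_0 + \sum_d (\beta_{d2} I_{d2} + \beta_{d3} I_{d3})\,
#'   \varphi_{d,c}}
#'
#' where `d` runs over the five EQ-5D dimensions, `I_{dl}` are the state's
#' dummy indicators, and `phi[d, c]` is a multiplicative scale parameter
#' that shrinks or amplifies the dimension-`d` decrements for respondents
#' in demographic cell `c`.  For identification each dimension's scale
#' parameters are positive and average exactly 1 over the cells, so the
#' `beta` coefficients carry the population-average decrements.  The
#' latent standard deviation is a log-linear 4th-order polynomial in the
#' mean, \eqn{\sigma = \exp(\gamma_0 + \gamma_1\mu + \ldots +
#' \gamma_4\mu^4)}, letting response noise depend flexibly on state
#' severity.
NULL

#' Model parameters
#'
#' @param beta0 Intercept (value of full health deviates from 1 by
#'   design; typically close to 1).
#' @param beta Numeric vector of the 10 decrement coefficients, ordered
#'   as [decrement_labels()].
#' @param gamma Numeric vector of the 5 log-SD polynomial coefficients.
#' @param phi Numeric matrix, 5 dimensions x G cells, all entries
#'   positive with each row averaging 1 (within 1e-10).  Row names must
#'   be [eq5d_dimensions]; column names are the cell labels.
#' @return Object of class `model_params`.
#' @export
model_params <- function(beta0, beta, gamma, phi) {
  beta <- as.numeric(beta)
  gamma <- as.numeric(gamma)
  stopifnot(length(beta0) == 1L, length(beta) == 10L, length(gamma) == 5L)
  names(beta) <- decrement_labels()
  names(gamma) <- paste0("gamma", 0:4)
  phi <- as.matrix(phi)
  if (nrow(phi) != 5L || is.null(colnames(phi))) {
    stop("phi must be a 5 x G matrix with cell-label column names",
         call. = FALSE)
  }
  rownames(phi) <- eq5d_dimensions
  if (any(phi <= 0)) stop("all phi must be positive", call. = FALSE)
  if (!phi_mean_one(phi)) {
    stop("each dimension's phi must average 1 over the cells", call. = FALSE)
  }
  structure(list(beta0 = as.numeric(beta0), beta = beta, gamma = gamma,
                 phi = phi, cells = colnames(phi)),
            class = "model_params")
}

# identification predicate, isolated so a weighted variant is a one-line
# change: unweighted arithmetic mean over cells equals 1 per dimension
phi_mean_one <- function(phi, tol = 1e-10) {
  all(abs(rowMeans(phi) - 1) <= tol)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tobit model parameters (G =", ncol(x$phi), "cells)\n")
  cat("  beta0:", format(x$beta0, digits = 4), "\n")
  cat("  beta: "); print(round(x$beta, 4))
  cat("  gamma:"); print(round(x$gamma, 4))
  cat("  phi (per-dimension scale by cell):\n")
  print(round(x$phi, 3))
  invisible(x)
}

#' Prior specification
#'
#' Vague normal priors with mean 0 and a common standard deviation for
#' the regression and variance-polynomial coefficients; log-normal priors
#' for the scale parameters with log-mean fixed at `-sd^2/2` so the prior
#' expectation of each scale parameter is exactly 1.
#'
#' @param beta_gamma_sd Prior SD for `beta0`, `beta` and `gamma`
#'   (default 10).
#' @param phi_log_sd Log-scale SD of the scale-parameter prior
#'   (default 0.4, giving log-mean -0.08).
#' @return Object of class `prior_spec` with elements `beta_gamma_sd`,
#'   `phi_log_sd`, `phi_log_mean`.
#' @export
prior_spec <- function(beta_gamma_sd = 10, phi_log_sd = 0.4) {
  stopifnot(beta_gamma_sd > 0, phi_log_sd > 0)
  structure(list(beta_gamma_sd = beta_gamma_sd,
                 phi_log_sd = phi_log_sd,
                 phi_log_mean = -phi_log_sd^2 / 2),
            class = "prior_spec")
}

#' Latent mean for one state/cell combination
#'
#' @param params A [model_params] object.
#' @param dummies Indicator vector of length 10 (see [encode_state()]).
#' @param cell Demographic cell label.
#' @return The latent mean `mu`.
#' @export
linear_predictor <- function(params, dummies, cell) {
  stopifnot(inherits(params, "model_params"), length(dummies) == 10L)
  if (!cell %in% params$cells) {
    stop("cell '", cell, "' not among the model's cells", call. = FALSE)
  }
  ph <- params$phi[, cell]
  contrib <- params$beta * dummies
  params$beta0 + sum((contrib[seq(1, 9, 2)] + contrib[seq(2, 10, 2)]) * ph)
}

#' Latent standard deviation as a polynomial in the mean
#'
#' @param params A [model_params] object (only `gamma` is used).
#' @param mu Latent mean(s).
#' @return `exp(gamma0 + gamma1*mu + ... + gamma4*mu^4)`, always
#'   positive.  Errors if the exponent exceeds overflow range (divergent
#'   parameters).
#' @export
scale_sd <- function(params, mu) {
  g <- unname(params$gamma)
  stopifnot(all(is.finite(mu)))
  # Horner form
  lg <- g[1] + mu * (g[2] + mu * (g[3] + mu * (g[4] + mu * g[5])))
  if (any(lg > 500)) {
    stop("log standard deviation overflow: divergent variance parameters",
         call. = FALSE)
  }
  exp(lg)
}

#' Tobit log-likelihood of one observation
#'
#' Interior observations (`value > censor`) contribute a normal log
#' density; censored observations (`value == censor`) contribute the log
#' normal CDF at the censoring bound, i.e. the probability mass of the
#' latent variable at or below the bound.
#'
#' @param value Observed TTO value(s), `>= censor`.
#' @param mu,sigma Latent mean(s) and SD(s), `sigma > 0`.
#' @param censor Censoring bound (default -1).
#' @return Log-likelihood contribution(s); vectorized.
#' @export
tobit_loglik_obs <- function(value, mu, sigma, censor = -1) {
  stopifnot(all(sigma > 0))
  if (any(value < censor)) {
    stop("observed value below the censoring bound ", censor, call. = FALSE)
  }
  cens <- value == censor
  out <- numeric(length(value))
  out[!cens] <- dnorm(value[!cens],
                      mean = rep_len(mu, length(value))[!cens],
                      sd = rep_len(sigma, length(value))[!cens], log = TRUE)
  out[cens] <- pnorm(censor,
                     mean = rep_len(mu, length(value))[cens],
                     sd = rep_len(sigma, length(value))[cens],
                     log.p = TRUE)
  out
}

# vectorized latent means for a design matrix X (n x 10) and cell index
# (n, into params$cells)
latent_means <- function(params, X, cell_idx) {
  G <- length(params$cells)
  # effective coefficients per cell: beta_{dl} * phi[d, c]
  eff <- matrix(rep(params$beta, G), nrow = G, byrow = TRUE) *
    t(params$phi)[, rep(seq_len(5L), each = 2L)]
  params$beta0 + rowSums(X * eff[cell_idx, , drop = FALSE])
}

#' Total log-likelihood of a dataset
#'
#' Sums [tobit_loglik_obs()] over all observations, with the latent mean
#' and SD computed per observation from the respondent's demographic cell
#' and the task's health state.
#'
#' @param params A [model_params] object.
#' @param data A [tto_data] object (QC-filtered).
#' @param censor Censoring bound (default -1).
#' @return Scalar log-likelihood (0 for an empty dataset).
#' @export
total_loglik <- function(params, data, censor = -1) {
  stopifnot(inherits(params, "model_params"), inherits(data, "tto_data"))
  if (nrow(data) == 0L) return(0)
  bad <- setdiff(unique(data$cell), params$cells)
  if (length(bad)) {
    stop("cell(s) not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- encode_state(data$state)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  cell_idx <- match(data$cell, params$cells)
  mu <- latent_means(params, X, cell_idx)
  sigma <- scale_sd(params, mu)
  sum(tobit_loglik_obs(data$value, mu, sigma, censor = censor))
}

#' Log prior density of the model parameters
#'
#' Normal log densities for `beta0`, `beta` and `gamma`; log-normal log
#' densities for the free scale-parameter coordinates.  Under the exact
#' mean-one constraint each dimension has G - 1 free coordinates (the
#' last cell is determined as `G - sum(others)`), and the prior is
#' evaluated on those free coordinates.
#'
#' @param params A [model_params] object; the mean-one constraint must
#'   hold and all phi must be positive.
#' @param priors A [prior_spec] object.
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(params, "model_params"), inherits(priors, "prior_spec"))
  if (any(params$phi <= 0)) stop("all phi must be positive", call. = FALSE)
  if (!phi_mean_one(params$phi)) {
    stop("phi mean-one constraint violated", call. = FALSE)
  }
  G <- ncol(params$phi)
  free <- params$phi[, seq_len(G - 1L), drop = FALSE]
  sum(dnorm(c(params$beta0, params$beta, params$gamma),
            0, priors$beta_gamma_sd, log = TRUE)) +
    sum(stats::dlnorm(free, meanlog = priors$phi_log_mean,
                      sdlog = priors$phi_log_sd, log = TRUE))
}

# ---- grouped sufficient statistics -----------------------------------------

# Collapse a dataset to unique (state, cell) groups with the Gaussian
# sufficient statistics of their observations.  Exact: within a group all
# observations share (mu, sigma), and the Tobit likelihood depends on the
# uncensored values only through their count, sum and sum of squares.
build_likelihood_groups <- function(data, cells) {
  stopifnot(inherits(data, "tto_data"))
  cell_idx <- match(data$cell, cells)
  if (anyNA(cell_idx)) {
    stop("cell(s) not in the model: ",
         paste(unique(data$cell[is.na(cell_idx)]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(data$state, cell_idx)
  uk <- sort(unique(key))
  ki <- match(key, uk)
  unc <- !data$censored
  v <- data$value
  tab <- function(w) as.numeric(rowsum(w, ki, reorder = TRUE))
  n_unc <- tab(as.numeric(unc))
  sum_v <- tab(v * unc)
  sum_v2 <- tab(v^2 * unc)
  n_cens <- tab(as.numeric(data$censored))
  parts <- strsplit(uk, " ", fixed = TRUE)
  states <- vapply(parts, `[[`, "", 1L)
  gcell <- as.integer(vapply(parts, `[[`, "", 2L))
  X <- encode_state(states)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, decrement_labels()))
  list(X = X, cell = gcell, n_unc = n_unc, sum_v = sum_v,
       sum_v2 = sum_v2, n_cens = n_cens, G = length(cells),
       cells = cells, n_obs = nrow(data))
}
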