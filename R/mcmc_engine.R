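#' @name mcmc_engine
#' @title Posterior sampling for the heteroskedastic Tobit model
#'
#' @description
#' The posterior is explored with a systematic-scan Gibbs sampler: the
#' intercept, the ten decrement coefficients and the five variance
#' coefficients are updated one at a time by Gaussian random-walk
#' Metropolis steps (optionally with antithetic, i.e. mirrored, proposal
#' innovations on alternate scans to reduce Monte-Carlo variance), and
#' each dimension's scale parameters are updated by univariate
#' stepping-out-and-shrinkage slice sampling on their free coordinates.
#' The mean-one constraint is kept exact at every draw by treating the
#' last demographic cell's scale parameter as derived:
#' `phi[d, G] = G - sum(phi[d, 1..G-1])`, with proposals that would make
#' any scale parameter non-positive rejected by truncation.  Step sizes
#' are tuned by Robbins-Monro adaptation towards a 0.44 acceptance rate
#' during burn-in only, so the retained chain is a time-homogeneous
#' sampler.
NULL

#' MCMC configuration
#'
#' @param n_chains Number of chains (default 3; at least 2 are needed for
#'   convergence diagnostics).
#' @param n_burnin Burn-in iterations per chain (default 10000).
#' @param n_total Total iterations per chain including burn-in
#'   (default 30000, so 20000 retained).
#' @param thin Thinning interval (default 1).
#' @param seed Master seed; all chain seeds and initialization jitter
#'   derive from it.
#' @param antithetic Use mirrored proposal innovations on alternate scans.
#'   Off by default: the mirrored-pair random walk is a Monte-Carlo
#'   variance-reduction device, but reusing the negated innovation after
#'   an acceptance-dependent step breaks detailed balance, and
#'   prior-recovery runs show a measurable distortion of the stationary
#'   distribution when acceptance rates are high.  The flag reproduces
#'   the device for comparison; validity-critical runs keep it off.
#' @param adapt Adapt Metropolis step sizes during burn-in (default TRUE).
#' @param step_init Initial step size for the 16 Metropolis blocks
#'   (scalar or length-16 vector, default 0.05).
#' @param slice_w Initial slice-sampling interval width (default 0.2).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_burnin = 10000L, n_total = 30000L,
                        thin = 1L, seed = 1L, antithetic = FALSE,
                        adapt = TRUE, step_init = 0.05, slice_w = 0.2) {
  n_chains <- as.integer(n_chains); n_burnin <- as.integer(n_burnin)
  n_total <- as.integer(n_total); thin <- as.integer(thin)
  if (!(n_total > n_burnin && n_burnin >= 0L)) {
    stop("need n_total > n_burnin >= 0", call. = FALSE)
  }
  if (n_chains < 1L) stop("need at least one chain", call. = FALSE)
  step_init <- rep_len(as.numeric(step_init), 16L)
  structure(list(n_chains = n_chains, n_burnin = n_burnin,
                 n_total = n_total, thin = thin, seed = as.integer(seed),
                 antithetic = isTRUE(antithetic), adapt = isTRUE(adapt),
                 step_init = step_init, slice_w = as.numeric(slice_w)),
            class = "mcmc_config")
}

n_retained <- function(config) {
  (config$n_total - config$n_burnin) %/% config$thin
}

# ---- parameter packing ------------------------------------------------------

param_names <- function(cells) {
  c("beta0", decrement_labels(), paste0("gamma", 0:4),
    as.vector(t(outer(eq5d_dimensions, cells,
                      function(d, c) paste0("phi_", d, "[", c, "]")))))
}

pack_params <- function(params) {
  c(params$beta0, params$beta, params$gamma,
    as.vector(t(params$phi)))  # dimension-major, cells within dimension
}

unpack_params <- function(vec, cells) {
  G <- length(cells)
  phi <- matrix(vec[17:(16 + 5 * G)], nrow = 5L, byrow = TRUE,
                dimnames = list(eq5d_dimensions, cells))
  model_params(beta0 = vec[1], beta = vec[2:11], gamma = vec[12:16],
               phi = phi)
}

# ---- generic scalar samplers (R reference implementations) -----------------

#' One Gaussian random-walk Metropolis update of a scalar
#'
#' @param current Current value; the log posterior must be finite there.
#' @param logpost Function of one scalar returning a log posterior
#'   density (up to a constant).
#' @param step Proposal standard deviation.
#' @param innovation Optional standard-normal innovation to use instead
#'   of drawing one; antithetic sampling passes the mirrored innovation
#'   `-z` of the previous update here.
#' @return List with `value` (new state), `accepted` (logical), and
#'   `innovation` (the innovation used, for mirroring).
#' @export
mh_update_scalar <- function(current, logpost, step, innovation = NULL) {
  lp0 <- logpost(current)
  if (!is.finite(lp0)) {
    stop("log posterior is not finite at the current value: invalid chain state",
         call. = FALSE)
  }
  z <- if (is.null(innovation)) rnorm(1L) else as.numeric(innovation)
  prop <- current + step * z
  lp1 <- logpost(prop)
  accepted <- is.finite(lp1) && log(runif(1L)) < (lp1 - lp0)
  list(value = if (accepted) prop else current,
       accepted = accepted, innovation = z)
}

#' One univariate stepping-out-and-shrinkage slice-sampling update
#'
#' @param x0 Current value with finite log density.
#' @param logpost Function of one scalar returning a log density.
#' @param w Initial interval width.
#' @param lower,upper Support bounds; the interval never expands past
#'   them.
#' @param max_expand Maximum stepping-out expansions before the update
#'   aborts (pathological target).
#' @return The new value.
#' @export
slice_update <- function(x0, logpost, w = 1, lower = -Inf, upper = Inf,
                         max_expand = 100L) {
  g <- function(x) if (x <= lower || x >= upper) -Inf else logpost(x)
  g0 <- g(x0)
  if (!is.finite(g0)) {
    stop("log density is not finite at the current value", call. = FALSE)
  }
  y <- g0 + log(runif(1L))
  L <- x0 - w * runif(1L)
  R <- L + w
  n_exp <- 0L
  while (L > lower && g(L) > y) {
    L <- L - w; n_exp <- n_exp + 1L
    if (n_exp > max_expand) stop("slice bracketing failed", call. = FALSE)
  }
  while (R < upper && g(R) > y) {
    R <- R + w; n_exp <- n_exp + 1L
    if (n_exp > 2L * max_expand) stop("slice bracketing failed", call. = FALSE)
  }
  L <- max(L, lower); R <- min(R, upper)
  for (i in seq_len(1000L)) {
    x1 <- L + runif(1L) * (R - L)
    if (g(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

#' Slice-update the free coordinates of one dimension's scale parameters
#'
#' Each dimension with G cells has G - 1 free scale coordinates; the last
#' cell is derived as `G - sum(free)` so the mean over cells is exactly
#' 1.  Each free coordinate is slice-sampled on its truncated support:
#' the coordinate itself and the implied derived cell must stay positive.
#'
#' @param phi_free Numeric vector of the G - 1 free coordinates (all
#'   positive, with derived cell positive).
#' @param logpost Function of a free-coordinate vector returning a log
#'   density.
#' @param w Slice interval width.
#' @return Updated free-coordinate vector.
#' @export
slice_update_phi <- function(phi_free, logpost, w = 0.2) {
  G <- length(phi_free) + 1L
  derived <- G - sum(phi_free)
  stopifnot(all(phi_free > 0), derived > 0)
  for (i in seq_along(phi_free)) {
    x0 <- phi_free[i]
    ub <- x0 + (G - sum(phi_free))  # keeps the derived cell positive
    target <- function(x) {
      v <- phi_free; v[i] <- x
      logpost(v)
    }
    phi_free[i] <- slice_update(x0, target, w = w, lower = 0, upper = ub)
  }
  phi_free
}

# ---- initialization ---------------------------------------------------------

#' Crude initial parameter values from a dataset
#'
#' The decrement coefficients are initialized by ordinary least squares
#' of the uncensored values on the state dummies, the log-SD intercept at
#' the log residual SD, and the scale parameters at 1 with a small jitter
#' on the free coordinates (the derived cell re-enforces the mean-one
#' constraint exactly).  Distinct seeds give distinct, overdispersed
#' starting points for multi-chain runs.
#'
#' @param data A QC-filtered [tto_data] object with at least one
#'   uncensored observation.
#' @param cells Demographic cell labels (default the 8 sex x age cells).
#' @param jitter_sd SD of the overdispersion jitter (0 disables).
#' @param seed Optional seed for the jitter.
#' @return A [model_params] object.
#' @export
initialize_params <- function(data, cells = demographic_cells(),
                              jitter_sd = 0.05, seed = NULL) {
  stopifnot(inherits(data, "tto_data"))
  unc <- data[!data$censored, , drop = FALSE]
  if (nrow(unc) == 0L) {
    stop("no uncensored observations: cannot initialize", call. = FALSE)
  }
  X <- encode_state(unc$state)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  fit <- stats::lm.fit(cbind(1, X), unc$value)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  res_sd <- max(sd(fit$residuals), 0.05)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  G <- length(cells)
  jit <- function(n, s) if (jitter_sd > 0) rnorm(n, 0, s) else numeric(n)
  beta0 <- cf[1] + jit(1, jitter_sd)
  beta <- cf[-1] + jit(10, jitter_sd)
  gamma <- c(log(res_sd) + jit(1, jitter_sd), numeric(4))
  repeat {
    free <- 1 + jit(G - 1L, jitter_sd)
    derived <- G - sum(free)
    if (all(free > 0) && derived > 0) break
  }
  phi <- matrix(rep(c(free, derived), each = 5L), nrow = 5L,
                dimnames = list(eq5d_dimensions, cells))
  model_params(beta0 = beta0, beta = beta, gamma = gamma, phi = phi)
}

# ---- chain driver -----------------------------------------------------------

#' Run one MCMC chain
#'
#' @param data A QC-filtered [tto_data] object (may be empty for
#'   prior-only sampling).
#' @param config An [mcmc_config].
#' @param chain_seed Seed for this chain's random-number stream.
#' @param init A [model_params] starting point.
#' @param priors A [prior_spec].
#' @param cells Demographic cell labels.
#' @param censor Censoring bound.
#' @return List with `draws` (matrix, retained iterations x parameters),
#'   `loglik` (vector), `accept_rate` and `final_step` (per Metropolis
#'   block).
#' @export
run_chain <- function(data, config, chain_seed, init = NULL,
                      priors = prior_spec(), cells = demographic_cells(),
                      censor = -1) {
  stopifnot(inherits(config, "mcmc_config"))
  if (is.null(init)) {
    init <- initialize_params(data, cells, seed = chain_seed)
  }
  stopifnot(inherits(init, "model_params"),
            identical(init$cells, cells))
  grp <- build_likelihood_groups(data, cells)
  Xi <- matrix(as.integer(grp$X), nrow = nrow(grp$X))
  res <- .run_tobit_chain_cpp(
    Xi, as.integer(grp$cell), grp$n_unc, grp$sum_v, grp$sum_v2,
    grp$n_cens, grp$G, pack_params(init), censor,
    config$n_burnin, config$n_total, config$thin,
    as.numeric(chain_seed), config$antithetic, config$adapt,
    config$step_init, config$slice_w,
    priors$beta_gamma_sd, priors$phi_log_mean, priors$phi_log_sd)
  pn <- param_names(cells)
  draws <- res$draws[, seq_along(pn), drop = FALSE]
  colnames(draws) <- pn
  list(draws = draws,
       loglik = res$draws[, length(pn) + 1L],
       accept_rate = setNames(res$accept_rate,
                              c("beta0", decrement_labels(),
                                paste0("gamma", 0:4))),
       final_step = res$final_step)
}

#' Fit the heteroskedastic Tobit model by MCMC
#'
#' Runs `config$n_chains` chains from overdispersed starting points,
#' discards burn-in, and computes split-chain potential scale reduction
#' factors for every parameter.
#'
#' @inheritParams run_chain
#' @param monitor Optional list with elements `original` and `updated`
#'   ([demographic_weights]); when given, weighted value-set decrements
#'   are monitored alongside the model parameters and stored as
#'   `$valuesets` (identical to running [monitor_valuesets()] on the
#'   stored draws afterwards).
#' @return Object of class `tobit_fit`: per-chain draw matrices, log
#'   likelihoods, acceptance rates, R-hat table, configuration, and cell
#'   labels.
#' @export
fit_tobit <- function(data, config = mcmc_config(), priors = prior_spec(),
                      cells = demographic_cells(), censor = -1,
                      monitor = NULL) {
  stopifnot(inherits(data, "tto_data"), inherits(config, "mcmc_config"))
  chains <- vector("list", config$n_chains)
  seeds <- as.numeric(config$seed) * 1000 + seq_len(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- if (nrow(data)) {
      initialize_params(data, cells, seed = seeds[ch])
    } else {
      prior_start(cells)
    }
    chains[[ch]] <- run_chain(data, config, chain_seed = seeds[ch],
                              init = init, priors = priors, cells = cells,
                              censor = censor)
  }
  fit <- structure(list(
    draws = lapply(chains, `[[`, "draws"),
    loglik = lapply(chains, `[[`, "loglik"),
    accept_rate = lapply(chains, `[[`, "accept_rate"),
    config = config, priors = priors, cells = cells, censor = censor,
    n_obs = nrow(data), n_respondents = n_respondents(data)),
    class = "tobit_fit")
  fit$rhat <- rhat_table(fit)
  if (!is.null(monitor)) {
    fit$valuesets <- monitor_valuesets(fit, monitor$original,
                                       monitor$updated)
  }
  fit
}

prior_start <- function(cells) {
  G <- length(cells)
  model_params(beta0 = 0, beta = numeric(10), gamma = numeric(5),
               phi = matrix(1, 5, G,
                            dimnames = list(eq5d_dimensions, cells)))
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("Heteroskedastic Tobit fit: %d chains x %d retained draws, %d observations\n",
              length(x$draws), nrow(x$draws[[1]]), x$n_obs))
  cat(sprintf("  max split R-hat: %.3f\n", max(x$rhat$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Stack all chains' draws into one matrix
#'
#' @param x A `tobit_fit`.
#' @param ... Unused.
#' @return Matrix with one row per retained draw (chains concatenated).
#' @export
as.matrix.tobit_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Posterior summary of a fit
#'
#' @param object A `tobit_fit`.
#' @param level Credible level (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return Data frame with posterior mean, SD, and credible bounds per
#'   parameter.
#' @export
summary.tobit_fit <- function(object, level = 0.95, ...) {
  m <- as.matrix(object)
  a <- (1 - level) / 2
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2L, sd),
             lo = apply(m, 2L, quantile, probs = a, type = 7),
             hi = apply(m, 2L, quantile, probs = 1 - a, type = 7),
             rhat = object$rhat$rhat[match(colnames(m),
                                           object$rhat$parameter)],
             row.names = NULL)
}

# ---- convergence diagnostics -----------------------------------------------

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical potential scale
#' reduction factor is computed over the resulting sub-chains, guarding
#' against within-chain trends.  Values near 1 indicate the chains agree.
#'
#' @param x A `tobit_fit`, or a list of per-chain numeric draw vectors.
#' @param parameter Parameter name (for a `tobit_fit`).
#' @return The R-hat value (>= 1 up to floating error); `NA` with a
#'   warning when all sub-chains have zero variance (undefined).
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  if (inherits(x, "tobit_fit")) {
    stopifnot(!is.null(parameter))
    x <- lapply(x$draws, function(m) m[, parameter])
  }
  stopifnot(is.list(x))
  if (length(x) < 2L) {
    stop("at least 2 chains are required for R-hat", call. = FALSE)
  }
  if (any(lengths(x) < 10L)) {
    stop("at least 10 retained draws per chain are required", call. = FALSE)
  }
  n2 <- min(lengths(x)) %/% 2L
  halves <- unlist(lapply(x, function(v) {
    v <- v[seq_len(2L * n2)]
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  if (W <= 0) {
    warning("zero within-chain variance: R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  B_over_n <- var(means)
  vplus <- (n2 - 1) / n2 * W + B_over_n
  sqrt(vplus / W)
}

#' R-hat for every parameter of a fit
#'
#' @param fit A `tobit_fit`.
#' @return Data frame with columns `parameter`, `rhat`.
#' @export
rhat_table <- function(fit) {
  stopifnot(inherits(fit, "tobit_fit"))
  pn <- colnames(fit$draws[[1]])
  rh <- vapply(pn, function(p) {
    if (length(fit$draws) < 2L) return(NA_real_)
    suppressWarnings(gelman_rubin(fit, p))
  }, numeric(1))
  data.frame(parameter = pn, rhat = unname(rh))
}
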