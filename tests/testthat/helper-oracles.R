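# Independent oracle implementations, deliberately written as plain
# scalar loops / closed forms so they share no code path with the
# package internals they check.

# one-pass scalar Tobit log-likelihood: loops observations, recomputes
# mu from scratch via explicit dummy arithmetic
oracle_total_loglik <- function(params, data, censor = -1) {
  params$beta <- unname(params$beta)
  params$gamma <- unname(params$gamma)
  total <- 0
  for (i in seq_len(nrow(data))) {
    lv <- as.integer(strsplit(data$state[i], "")[[1]])
    mu <- params$beta0
    for (d in 1:5) {
      contrib <- 0
      if (lv[d] == 2) contrib <- params$beta[2 * d - 1]
      if (lv[d] == 3) contrib <- params$beta[2 * d]
      mu <- mu + contrib * params$phi[d, data$cell[i]]
    }
    g <- params$gamma
    sg <- exp(g[1] + g[2] * mu + g[3] * mu^2 + g[4] * mu^3 + g[5] * mu^4)
    v <- data$value[i]
    total <- total + if (v == censor) {
      pnorm((censor - mu) / sg, log.p = TRUE)
    } else {
      -log(sg) - 0.5 * log(2 * pi) - (v - mu)^2 / (2 * sg^2)
    }
  }
  total
}

# plain homoskedastic Tobit log-likelihood (no scale parameters, constant
# sigma), an independent limit-case reference
oracle_plain_tobit <- function(beta0, beta, sigma, data, censor = -1) {
  X <- t(vapply(strsplit(data$state, ""), function(lv) {
    lv <- as.integer(lv)
    as.numeric(c(rbind(lv == 2, lv == 3)))
  }, numeric(10)))
  mu <- beta0 + as.vector(X %*% beta)
  cens <- data$value == censor
  sum(pnorm((censor - mu[cens]) / sigma, log.p = TRUE)) +
    sum(dnorm(data$value[!cens], mu[!cens], sigma, log = TRUE))
}

# least-squares slope via the normal equations
oracle_ols_slope <- function(values, misery) {
  A <- cbind(1, misery)
  solve(t(A) %*% A, t(A) %*% values)[2]
}

# batch-means Monte-Carlo standard error for a correlated chain
batch_se <- function(x, n_batch = 50) {
  n <- length(x) %/% n_batch * n_batch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  sd(bm) / sqrt(n_batch)
}

# E[observed value] under the censored-normal model, by quadrature
oracle_tobit_mean <- function(mu, sigma, censor = -1) {
  interior <- stats::integrate(function(v) v * dnorm(v, mu, sigma),
                               lower = censor, upper = mu + 12 * sigma,
                               rel.tol = 1e-10)$value
  interior + censor * pnorm((censor - mu) / sigma)
}
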