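test_that("parameter container enforces positivity and the mean-one constraint", {
  p <- random_params(seed = 1)
  expect_s3_class(p, "model_params")
  expect_equal(unname(rowMeans(p$phi)), rep(1, 5), tolerance = 1e-10)
  bad_phi <- p$phi
  bad_phi[2, ] <- bad_phi[2, ] * 1.05
  expect_error(model_params(p$beta0, p$beta, p$gamma, bad_phi), "average 1")
  neg_phi <- p$phi
  neg_phi[1, 1] <- -neg_phi[1, 1]
  expect_error(model_params(p$beta0, p$beta, p$gamma, neg_phi), "positive")
})

test_that("log-normal prior for scale parameters has expectation one", {
  pr <- prior_spec()
  expect_equal(pr$phi_log_mean, -0.08)
  expect_equal(pr$phi_log_mean, -pr$phi_log_sd^2 / 2)
  # E[lognormal] = exp(mu + sigma^2/2) = 1 exactly
  expect_equal(exp(pr$phi_log_mean + pr$phi_log_sd^2 / 2), 1)
})

test_that("linear predictor applies scale parameters to the dummy contributions", {
  cells <- demographic_cells()
  phi <- matrix(1, 5, 8, dimnames = list(eq5d_dimensions, cells))
  phi[1, ] <- c(1.25, rep((8 - 1.25) / 7, 7))
  p <- model_params(beta0 = 1, beta = c(0, -0.4, rep(0, 8)),
                    gamma = rep(0, 5), phi = phi)
  expect_equal(linear_predictor(p, encode_state("31111"), "Male 18-34"),
               1 + (-0.4) * 1.25)
  expect_equal(linear_predictor(p, encode_state("11111"), "Female 75+"), 1)
  expect_error(linear_predictor(p, encode_state("11111"), "Male 95+"),
               "Male 95\\+")
  # all-unit scale parameters reduce to the homogeneous model for every state
  pr <- random_params(seed = 7)
  unit <- model_params(pr$beta0, pr$beta, pr$gamma,
                       matrix(1, 5, 8, dimnames = dimnames(pr$phi)))
  states <- all_eq5d_states()
  X <- encode_state(states)
  hom <- unit$beta0 + as.vector(X %*% unit$beta)
  for (cell in cells[c(1, 5, 8)]) {
    got <- vapply(seq_len(243), function(i) {
      linear_predictor(unit, X[i, ], cell)
    }, numeric(1))
    expect_equal(got, hom, tolerance = 1e-12)
  }
})

test_that("latent SD follows the quartic log-polynomial", {
  p <- random_params(seed = 2)
  p$gamma <- c(log(0.3), 0, 0, 0, 0)
  expect_equal(scale_sd(p, c(-5, 0, 2)), rep(0.3, 3))
  p$gamma <- c(0, 1, 0, 0, 0)
  expect_equal(scale_sd(p, 0), 1)
  p$gamma <- c(0.1, -0.2, 0.05, 0, 0)
  expect_equal(scale_sd(p, 0.5), exp(0.0125))
  # Horner evaluation against naive powers on random coefficients
  set.seed(11)
  for (i in 1:20) {
    p$gamma <- rnorm(5, 0, 0.3)
    mu <- runif(1, -1, 1.2)
    expect_equal(scale_sd(p, mu),
                 exp(sum(p$gamma * mu^(0:4))), tolerance = 1e-12)
  }
  p$gamma <- c(1000, 0, 0, 0, 0)
  expect_error(scale_sd(p, 1), "overflow")
})

test_that("per-observation likelihood splits density and censoring mass correctly", {
  # censored at -1 under a standard normal latent: log Phi(-1)
  expect_equal(tobit_loglik_obs(-1, 0, 1), -1.8410216450092636,
               tolerance = 1e-10)
  # interior point: standard normal log density at 0.5
  expect_equal(tobit_loglik_obs(0.5, 0, 1), -0.9189385332046727 - 0.125,
               tolerance = 1e-12)
  # zero residual: -log s - log sqrt(2 pi)
  for (s in c(0.1, 1, 3)) {
    expect_equal(tobit_loglik_obs(0.5, 0.5, s),
                 -log(s) - 0.5 * log(2 * pi), tolerance = 1e-12)
  }
  expect_error(tobit_loglik_obs(-1.2, 0, 1), "below")
})

test_that("an uncensored observation's likelihood peaks at mu equal to the value", {
  mus <- seq(-1, 1.5, by = 0.01)
  ll <- tobit_loglik_obs(rep(0.37, length(mus)), mus, 0.4)
  expect_equal(mus[which.max(ll)], 0.37, tolerance = 1e-9)
})

test_that("censored mass and interior density integrate to one", {
  set.seed(8)
  for (i in 1:10) {
    mu <- runif(1, -2, 1)
    sg <- runif(1, 0.1, 1)
    mass <- exp(tobit_loglik_obs(-1, mu, sg))
    interior <- stats::integrate(function(v) dnorm(v, mu, sg),
                                 lower = -1, upper = Inf)$value
    expect_equal(mass + interior, 1, tolerance = 1e-6)
  }
})

test_that("total log-likelihood matches an independent scalar loop", {
  for (seed in 1:6) {
    p <- random_params(seed = seed)
    d <- random_dataset(seed = seed + 100, n_resp = 6, n_obs = 5)
    expect_equal(total_loglik(p, d), oracle_total_loglik(p, d),
                 tolerance = 1e-10)
  }
  expect_equal(total_loglik(random_params(1), empty_tto()), 0)
  d1 <- tiny_tto("r1", "21321", 0.25)
  p <- random_params(3)
  mu <- linear_predictor(p, encode_state("21321"), "Male 18-34")
  expect_equal(total_loglik(p, d1),
               tobit_loglik_obs(0.25, mu, scale_sd(p, mu)))
})

test_that("unit scale parameters and constant variance reduce to a plain Tobit", {
  for (seed in 1:4) {
    pr <- random_params(seed)
    sigma <- 0.35
    p <- model_params(pr$beta0, pr$beta, c(log(sigma), 0, 0, 0, 0),
                      matrix(1, 5, 8, dimnames = dimnames(pr$phi)))
    d <- random_dataset(seed + 50, n_resp = 10, n_obs = 6)
    expect_equal(total_loglik(p, d),
                 oracle_plain_tobit(p$beta0, p$beta, sigma, d),
                 tolerance = 1e-8)
  }
})

test_that("grouped sufficient-statistic likelihood agrees with the direct sum", {
  for (seed in c(2, 9)) {
    p <- random_params(seed)
    d <- random_dataset(seed, n_resp = 15, n_obs = 10)
    grp <- valuesetdrift:::build_likelihood_groups(d, p$cells)
    ll_cpp <- valuesetdrift:::.tobit_group_loglik_cpp(
      matrix(as.integer(grp$X), nrow = nrow(grp$X)), as.integer(grp$cell),
      grp$n_unc, grp$sum_v, grp$sum_v2, grp$n_cens, grp$G,
      valuesetdrift:::pack_params(p), -1)
    expect_equal(ll_cpp, total_loglik(p, d), tolerance = 1e-10)
  }
})

test_that("log prior evaluates free coordinates and enforces the constraint", {
  cells <- demographic_cells()
  p0 <- model_params(0, numeric(10), numeric(5),
                     matrix(1, 5, 8, dimnames = list(eq5d_dimensions, cells)))
  # closed form: 16 normal log densities at the mode + 35 log-normal
  # log densities at 1
  expected <- 16 * (-log(10) - 0.5 * log(2 * pi)) +
    35 * (-log(0.4) - 0.5 * log(2 * pi) - 0.08^2 / (2 * 0.4^2))
  expect_equal(log_prior(p0, prior_spec()), expected, tolerance = 1e-12)
  # doubling the prior SD lowers each beta/gamma term by log 2 at the mode
  expect_equal(log_prior(p0, prior_spec(beta_gamma_sd = 20)) -
                 log_prior(p0, prior_spec(beta_gamma_sd = 10)),
               -16 * log(2), tolerance = 1e-12)
  bad <- p0
  bad$phi[1, ] <- bad$phi[1, ] + 0.1
  expect_error(log_prior(bad, prior_spec()), "constraint")
})
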