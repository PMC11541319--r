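make_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      d <- simulate_study(scaled_truth("UK", n = 120, seed = 55,
                                       contaminate = FALSE), seed = 55)
      memo <<- fit_tobit(d, mcmc_config(n_chains = 2, n_burnin = 150,
                                        n_total = 650, seed = 55))
    }
    memo
  }
})

test_that("weighted decrements average the scale parameters over cells", {
  w5 <- demographic_weights(c(a = 0.5, b = 0.5))
  w9 <- demographic_weights(c(a = 0.9, b = 0.1))
  phi <- c(a = 0.5, b = 1.5)
  expect_equal(weighted_decrement(-0.2, phi, w5), -0.2)
  expect_equal(weighted_decrement(-0.2, phi, w9), -0.2 * (0.45 + 0.15))
  expect_equal(weighted_decrement(-0.2, c(a = 1, b = 1), w9), -0.2)
  expect_error(weighted_decrement(-0.2, c(a = 1, b = 1, c = 1), w5),
               "missing cell.*c")
})

test_that("identical weightings give exactly zero difference draws", {
  fit <- make_fit()
  w <- eq_weights("UK-1997")
  vs <- monitor_valuesets(fit, w, w)
  expect_true(all(vs$diff == 0))
  s <- summarize_valuesets(vs)
  expect_true(all(s$diff_mean == 0 & s$diff_lo == 0 & s$diff_hi == 0))
  expect_false(any(s$significant))
})

test_that("difference draws satisfy the weighted-contrast identity per draw", {
  fit <- make_fit()
  wo <- eq_weights("UK-1997")
  wu <- eq_weights("UK-2022")
  vs <- monitor_valuesets(fit, wo, wu)
  m <- as.matrix(fit)
  cells <- fit$cells
  dw <- as.numeric(wu[cells]) - as.numeric(wo[cells])
  labs <- decrement_labels()
  for (j in c(1, 4, 10)) {
    d <- (j + 1) %/% 2
    ph <- m[, paste0("phi_", eq5d_dimensions[d], "[", cells, "]")]
    expected <- m[, labs[j]] * as.vector(ph %*% dw)
    expect_equal(vs$diff[, j], unname(expected), tolerance = 1e-12)
  }
  expect_equal(vs$diff, vs$updated - vs$original)
})

test_that("constant scale parameters make reweighting inert", {
  # one hand-built draw: phi identical across cells
  cells <- demographic_cells()
  pn <- valuesetdrift:::param_names(cells)
  draw <- c(0.9, -seq(0.05, 0.5, length.out = 10), c(-1, 0, 0, 0, 0),
            rep(1, 40))
  m <- matrix(rep(draw, each = 200), nrow = 200, dimnames = list(NULL, pn))
  vs <- monitor_valuesets(m, eq_weights("UK-1997"), eq_weights("UK-2022"))
  expect_true(all(abs(vs$diff) < 1e-15))
  # and a hand-computed weighted decrement for a non-constant draw
  draw2 <- draw
  phi_mo <- c(1.2, 1.1, 0.9, 0.8, 1.25, 1.05, 0.95, 0.75)
  phi_mo <- phi_mo / mean(phi_mo)
  draw2[17:24] <- phi_mo
  m2 <- matrix(rep(draw2, each = 200), nrow = 200,
               dimnames = list(NULL, pn))
  w <- eq_weights("UK-1997")
  vs2 <- monitor_valuesets(m2, w, w)
  expect_equal(unname(vs2$original[1, "MO2"]),
               draw2[2] * sum(as.numeric(w[cells]) * phi_mo),
               tolerance = 1e-12)
})

test_that("inline monitoring during fitting equals post-hoc monitoring", {
  d <- simulate_study(scaled_truth("UK", n = 60, seed = 77,
                                   contaminate = FALSE), seed = 77)
  wo <- eq_weights("UK-1997")
  wu <- eq_weights("UK-2022")
  fit <- fit_tobit(d, mcmc_config(n_chains = 2, n_burnin = 100,
                                  n_total = 300, seed = 77),
                   monitor = list(original = wo, updated = wu))
  post <- monitor_valuesets(fit, wo, wu)
  expect_identical(fit$valuesets$original, post$original)
  expect_identical(fit$valuesets$diff, post$diff)
})

test_that("credible summaries are percentile-exact and order-invariant", {
  pn <- valuesetdrift:::param_names(demographic_cells())
  # constant draws: degenerate intervals
  draw <- c(1, rep(-0.3, 10), rep(0, 5), rep(1, 40))
  m <- matrix(rep(draw, each = 150), nrow = 150,
              dimnames = list(NULL, pn))
  vs <- monitor_valuesets(m, eq_weights("UK-1997"), eq_weights("UK-2022"))
  s <- summarize_valuesets(vs)
  expect_equal(s$original_mean, rep(-0.3, 10))
  expect_equal(s$original_lo, s$original_hi)
  # symmetric +/-1 draws: interval comprises 0, not significant
  vs$diff[] <- rep(c(-1, 1), length.out = nrow(vs$diff))
  s2 <- summarize_valuesets(vs)
  expect_false(any(s2$significant))
  expect_true(all(s2$diff_lo < 0 & s2$diff_hi > 0))
  # large-sample normal draws: interval near +/-1.96
  set.seed(12)
  z <- rnorm(10000)
  vs$diff <- matrix(z, nrow = 10000, ncol = 10,
                    dimnames = list(NULL, decrement_labels()))
  vs$original <- vs$updated <- vs$diff
  s3 <- summarize_valuesets(vs)
  expect_lt(max(abs(s3$diff_lo + 1.959964)), 0.05)
  expect_lt(max(abs(s3$diff_hi - 1.959964)), 0.05)
  # shuffle invariance
  perm <- sample(10000)
  vs_shuffled <- vs
  for (nm in c("original", "updated", "diff")) {
    vs_shuffled[[nm]] <- vs[[nm]][perm, , drop = FALSE]
  }
  expect_equal(summarize_valuesets(vs_shuffled), s3, tolerance = 1e-12)
  # too few draws for the requested tails
  vs_small <- vs
  for (nm in c("original", "updated", "diff")) {
    vs_small[[nm]] <- vs[[nm]][1:20, , drop = FALSE]
  }
  expect_error(summarize_valuesets(vs_small), "too few draws")
})

test_that("state-value prediction anchors at the intercept and adds decrements", {
  p <- random_params(seed = 13)
  w <- eq_weights("UK-1997")
  expect_equal(predict_state_value(p, "11111", w), p$beta0)
  dec <- vapply(1:10, function(j) {
    weighted_decrement(p$beta[j], p$phi[(j + 1) %/% 2, ], w)
  }, numeric(1))
  expect_equal(predict_state_value(p, "33333", w),
               p$beta0 + sum(dec[seq(2, 10, 2)]))
  expect_equal(predict_state_value(p, "21111", w) -
                 predict_state_value(p, "11111", w), dec[1])
  # summary-table input
  s <- data.frame(label = decrement_labels(),
                  updated_mean = -seq(0.02, 0.2, length.out = 10))
  expect_equal(predict_state_value(s, "11111", intercept = 1), 1)
  expect_equal(predict_state_value(s, "31111", intercept = 1),
               1 + s$updated_mean[2])
  expect_error(predict_state_value(p, "99999", w), "99999")
})
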