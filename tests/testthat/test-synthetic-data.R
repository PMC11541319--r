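test_that("design pools have the documented cardinalities and coverage", {
  pool <- design_pool_45()
  expect_length(pool, 45L)
  expect_length(unique(pool), 45L)
  expect_true("33333" %in% pool)
  expect_setequal(unique(misery_index(pool)), 6:15)
  fixed <- design_fixed_17()
  expect_length(fixed, 17L)
  expect_true(all(fixed %in% pool))
  expect_true("33333" %in% fixed)
})

test_that("default truths are valid and carry each study's design dialect", {
  uk <- default_truth("UK")
  expect_equal(uk$dialect, "sampled-12-of-45")
  expect_equal(uk$n_tasks, 12L)
  expect_equal(length(names(uk$composition)), 8L)
  jp <- default_truth("JPN")
  expect_equal(jp$dialect, "fixed-17")
  expect_equal(jp$n_tasks, 17L)
  us <- default_truth("US")
  expect_equal(us$low_completer_frac, 0)
  for (tr in list(uk, jp, us)) {
    expect_s3_class(tr$params, "model_params")
    expect_equal(unname(rowMeans(tr$params$phi)), rep(1, 5),
                 tolerance = 1e-12)
    expect_true(all(tr$params$phi > 0.7 & tr$params$phi < 1.3))
    expect_equal(sum(tr$composition), 1, tolerance = 1e-12)
    # latent SD stays in the intended 0.2-0.5 band over the value range
    sg <- scale_sd(tr$params, seq(-0.5, 1, by = 0.05))
    expect_true(all(sg > 0.15 & sg < 0.55))
  }
  expect_error(default_truth("FR"), "arg")
})

test_that("design dialects produce the promised task lists deterministically", {
  set.seed(1)
  fixed <- make_design("fixed-17", 20)
  expect_true(all(vapply(fixed, identical, logical(1), fixed[[1]])))
  expect_length(fixed[[1]], 17L)
  set.seed(2)
  sampled <- make_design("sampled-12-of-45", 50)
  pool <- design_pool_45()
  for (s in sampled) {
    expect_length(s, 12L)
    expect_length(unique(s), 12L)
    expect_true(all(s %in% pool))
  }
  set.seed(9); d1 <- make_design("sampled-12-of-45", 10)
  set.seed(9); d2 <- make_design("sampled-12-of-45", 10)
  expect_identical(d1, d2)
})

test_that("simulation is fully deterministic under a fixed seed", {
  tr <- scaled_truth("UK", n = 50, seed = 3)
  d1 <- simulate_study(tr, seed = 3)
  d2 <- simulate_study(tr, seed = 3)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_study(tr, seed = 4)
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("near-noiseless simulation reproduces the latent means per state", {
  tr <- scaled_truth("JPN", n = 400, seed = 6, contaminate = FALSE)
  tr$params <- model_params(tr$params$beta0, tr$params$beta,
                            c(-20, 0, 0, 0, 0), tr$params$phi)
  d <- simulate_study(tr, seed = 6)
  X <- encode_state(d$state)
  mu <- valuesetdrift:::latent_means(tr$params, X,
                                     match(d$cell, tr$params$cells))
  expect_lt(max(abs(d$value - mu)), 0.01)
  agg <- tapply(d$value, paste(d$state, d$cell),
                mean) -
    tapply(mu, paste(d$state, d$cell), mean)
  expect_lt(max(abs(agg)), 0.01)
})

test_that("deep censoring pins every observation at the bound", {
  cells <- demographic_cells()
  p <- model_params(beta0 = -3, beta = numeric(10),
                    gamma = c(log(0.1), 0, 0, 0, 0),
                    phi = matrix(1, 5, 8,
                                 dimnames = list(eq5d_dimensions, cells)))
  tr <- truth_scenario(p, eq_weights("UK-1997"), dialect = "fixed-17",
                       n_respondents = 40)
  d <- simulate_study(tr, seed = 8)
  expect_equal(censoring_rate(d), 1)
  expect_true(all(d$value == -1))
})

test_that("censoring rate is one half when the latent mean sits at the bound", {
  cells <- demographic_cells()
  p <- model_params(beta0 = -1, beta = numeric(10),
                    gamma = c(log(0.4), 0, 0, 0, 0),
                    phi = matrix(1, 5, 8,
                                 dimnames = list(eq5d_dimensions, cells)))
  tr <- truth_scenario(p, eq_weights("UK-1997"), dialect = "fixed-17",
                       n_respondents = 600)
  d <- simulate_study(tr, seed = 12)
  n <- nrow(d)
  se <- sqrt(0.25 / n)
  expect_lt(abs(censoring_rate(d) - 0.5), 3 * se)
  expect_warning(r <- censoring_rate(empty_tto()), "undefined")
  expect_true(is.na(r))
})

test_that("empirical state means converge to the censored-normal expectation", {
  tr <- scaled_truth("JPN", n = 3000, seed = 14, contaminate = FALSE)
  d <- simulate_study(tr, seed = 14)
  # the worst state in one well-populated cell (everyone values it under
  # the fixed-17 dialect)
  cell <- "Female 35-54"
  sel <- d$state == "33333" & d$cell == cell
  expect_gt(sum(sel), 300)
  mu <- linear_predictor(tr$params, encode_state("33333"), cell)
  sg <- scale_sd(tr$params, mu)
  expected <- oracle_tobit_mean(mu, sg)
  emp_se <- sd(d$value[sel]) / sqrt(sum(sel))
  expect_lt(abs(mean(d$value[sel]) - expected), 3 * emp_se)
})

test_that("demographic cell frequencies follow the sampling composition", {
  tr <- scaled_truth("UK", n = 10000, seed = 16, contaminate = FALSE)
  d <- simulate_study(tr, seed = 16)
  resp <- d[!duplicated(d$respondent_id), ]
  counts <- table(factor(resp$cell, levels = names(tr$composition)))
  p <- stats::chisq.test(counts, p = as.numeric(tr$composition))$p.value
  expect_gt(p, 0.001)
})

test_that("planted contaminants are detectable with high sensitivity across seeds", {
  hits <- 0L
  total <- 0L
  for (seed in 1:5) {
    tr <- scaled_truth("UK", n = 120, seed = seed)
    tr$low_completer_frac <- 6 / 120
    tr$positive_slope_frac <- 4 / 120
    d <- simulate_study(tr, seed = seed)
    qc <- run_qc(d)
    planted_low <- attr(d, "planted_low")
    planted_slope <- attr(d, "planted_slope")
    dec <- qc$report$decisions
    hits <- hits + sum(planted_low %in%
                         dec$respondent_id[dec$rule == "min_obs"]) +
      sum(planted_slope %in%
            dec$respondent_id[dec$rule == "positive_slope"])
    total <- total + length(planted_low) + length(planted_slope)
  }
  expect_gte(hits / total, 0.95)
})
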