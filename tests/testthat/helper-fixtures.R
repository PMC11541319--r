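# small in-code fixtures shared across test files

tiny_tto <- function(ids, states, values, sex = "Male", age_group = "18-34",
                     dialect = "sampled") {
  tto_data(data.frame(respondent_id = ids, sex = sex,
                      age_group = age_group, state = states,
                      value = values, stringsAsFactors = FALSE),
           dialect = dialect, provenance = "test fixture")
}

empty_tto <- function() {
  tto_data(data.frame(respondent_id = character(), sex = character(),
                      age_group = character(), state = character(),
                      value = numeric(), stringsAsFactors = FALSE))
}

# valid random parameters over the default 8 cells
random_params <- function(seed = 1, cells = demographic_cells()) {
  set.seed(seed)
  G <- length(cells)
  repeat {
    free <- exp(rnorm(G - 1, -0.02, 0.15))
    derived <- G - sum(free)
    if (derived > 0) break
  }
  phi <- matrix(NA_real_, 5, G, dimnames = list(eq5d_dimensions, cells))
  for (d in 1:5) {
    repeat {
      f <- exp(rnorm(G - 1, -0.02, 0.15))
      if (G - sum(f) > 0) break
    }
    phi[d, ] <- c(f, G - sum(f))
  }
  model_params(beta0 = runif(1, 0.7, 1.1),
               beta = -runif(10, 0.02, 0.5),
               gamma = c(runif(1, -1.5, -0.7), runif(1, -0.7, 0),
                         runif(1, -0.1, 0.1), 0, 0),
               phi = phi)
}

# a small random dataset with censored observations
random_dataset <- function(seed = 1, n_resp = 8, n_obs = 6) {
  set.seed(seed)
  cells <- demographic_cells()
  states <- all_eq5d_states()
  ids <- rep(sprintf("r%02d", seq_len(n_resp)), each = n_obs)
  cell <- rep(sample(cells, n_resp, replace = TRUE), each = n_obs)
  parts <- strsplit(cell, " ", fixed = TRUE)
  value <- round(runif(n_resp * n_obs, -1.3, 1), 3)
  value[value < -1] <- -1
  tto_data(data.frame(
    respondent_id = ids,
    sex = vapply(parts, `[[`, "", 1),
    age_group = vapply(parts, `[[`, "", 2),
    state = sample(states, n_resp * n_obs, replace = TRUE),
    value = value, stringsAsFactors = FALSE))
}

scaled_truth <- function(style = "UK", n = 1000, seed = 1,
                         params = NULL, contaminate = TRUE) {
  tr <- default_truth(style)
  truth_scenario(params %||% tr$params, tr$composition,
                 dialect = tr$dialect, n_respondents = n,
                 low_completer_frac = if (contaminate) tr$low_completer_frac else 0,
                 positive_slope_frac = if (contaminate) tr$positive_slope_frac else 0,
                 seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
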