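#' @name pipeline
#' @title End-to-end analysis pipeline
#'
#' @description
#' [run_pipeline()] chains the full workflow -- obtain data (from file or
#' by simulation), respondent QC, MCMC fitting, demographic reweighting
#' -- and writes a reproducible artifact bundle: QC report, posterior
#' draws, convergence table, value-set comparison table, and a manifest
#' holding the seed and settings so a run can be reproduced exactly.
NULL

resolve_weights <- function(x) {
  if (inherits(x, "demographic_weights")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(read_weights(x))
    ok <- tryCatch(eq_weights(x), error = function(e) NULL)
    if (!is.null(ok)) return(ok)
    stop("weights file not found and no bundled weights named '", x, "'",
         call. = FALSE)
  }
  stop("cannot interpret weights specification", call. = FALSE)
}

resolve_input <- function(input, seed) {
  if (inherits(input, "tto_data")) return(input)
  if (inherits(input, "truth_scenario")) {
    return(simulate_study(input, seed = seed))
  }
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) {
      stop("input data file not found: ", input, call. = FALSE)
    }
    return(read_tto_table(input))
  }
  if (is.list(input) && !is.null(input$path)) {
    if (!file.exists(input$path)) {
      stop("input data file not found: ", input$path, call. = FALSE)
    }
    return(read_tto_table(input$path, col_map = input$col_map,
                          sep = input$sep %||% ","))
  }
  stop("cannot interpret pipeline input", call. = FALSE)
}

#' Run the full valuation-analysis pipeline
#'
#' @param input A [tto_data] object, a [truth_scenario] (simulated at the
#'   pipeline seed), a path to a canonical TTO table, or a list with
#'   `path`, `col_map`, `sep` for file input.
#' @param weights_original,weights_updated [demographic_weights], a
#'   bundled label (see [eq_weights()]), or a file path.
#' @param out_dir Output directory (created if needed).
#' @param mcmc An [mcmc_config]; its seed is the run's master seed.
#' @param priors A [prior_spec].
#' @param min_obs QC minimum task count.
#' @param rhat_warn Convergence gate: a warning (not an error) is raised
#'   and recorded when any split R-hat exceeds this (default 1.05);
#'   outputs are still written.
#' @return Invisibly, a `pipeline_bundle`: the QC report, fit, value-set
#'   summary, manifest, and output file paths.
#' @export
run_pipeline <- function(input, weights_original, weights_updated,
                         out_dir, mcmc = mcmc_config(),
                         priors = prior_spec(), min_obs = 10L,
                         rhat_warn = 1.05) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  wo <- resolve_weights(weights_original)
  wu <- resolve_weights(weights_updated)
  if (identical(attr(wo, "label"), attr(wu, "label")) &&
      !isTRUE(all.equal(unclass(wo), unclass(wu)))) {
    stop("weight labels must be distinct when compositions differ",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- resolve_input(input, seed = mcmc$seed)
  qc <- run_qc(data, min_obs = min_obs)
  fit <- fit_tobit(qc$data, config = mcmc, priors = priors,
                   monitor = list(original = wo, updated = wu))
  vs_summary <- summarize_valuesets(fit$valuesets)
  paths <- list(
    qc_report = file.path(out_dir, "qc_report.json"),
    draws = file.path(out_dir, "draws.csv"),
    rhat = file.path(out_dir, "rhat.csv"),
    valueset = file.path(out_dir, "valueset.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  jsonlite::write_json(qc_report_to_list(qc$report), paths$qc_report,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_draws(fit, paths$draws)
  write.csv(fit$rhat, paths$rhat, row.names = FALSE)
  write_valueset(vs_summary, paths$valueset)
  max_rhat <- suppressWarnings(max(fit$rhat$rhat, na.rm = TRUE))
  converged <- is.finite(max_rhat) && max_rhat <= rhat_warn
  manifest <- list(
    package = "valuesetdrift",
    version = as.character(utils::packageVersion("valuesetdrift")),
    seed = mcmc$seed,
    mcmc = mcmc[c("n_chains", "n_burnin", "n_total", "thin",
                  "antithetic", "adapt", "slice_w")],
    priors = unclass(priors),
    min_obs = min_obs,
    weights_original = attr(wo, "label"),
    weights_updated = attr(wu, "label"),
    input = if (inherits(input, "truth_scenario")) {
      list(type = "simulated", dialect = input$dialect,
           n_respondents = input$n_respondents)
    } else list(type = "data", provenance = attr(data, "provenance")),
    n_obs = fit$n_obs, n_respondents = fit$n_respondents,
    max_rhat = max_rhat, converged = converged,
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!converged) {
    warning(sprintf("convergence warning: max split R-hat %.3f > %.2f",
                    max_rhat, rhat_warn), call. = FALSE)
  }
  invisible(structure(list(qc_report = qc$report, fit = fit,
                           valueset_summary = vs_summary,
                           manifest = manifest, paths = paths),
                      class = "pipeline_bundle"))
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline bundle in", dirname(x$paths$manifest), "\n")
  print(x$qc_report)
  cat(report(x), sep = "\n")
  invisible(x)
}

fmt2 <- function(x) {
  # round half to even at 2 decimals, then fixed-format
  formatC(round(x, 2L), format = "f", digits = 2L)
}

#' Human-readable value-set comparison report
#'
#' One row per decrement with `mean (lo - hi)` cells for the original
#' weighting, the updated weighting, and their difference, rounded to 2
#' decimals (half-even); differences whose credible interval excludes 0
#' are starred.
#'
#' @param bundle A `pipeline_bundle` or a value-set summary data frame.
#' @return Character vector of report lines.
#' @export
report <- function(bundle) {
  if (inherits(bundle, "pipeline_bundle")) {
    need <- c("qc_report", "fit", "valueset_summary", "manifest")
    miss <- need[!vapply(need, function(n) !is.null(bundle[[n]]),
                         logical(1))]
    if (length(miss)) {
      stop("incomplete bundle, missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    s <- bundle$valueset_summary
    head_labels <- c(bundle$manifest$weights_original %||% "original",
                     bundle$manifest$weights_updated %||% "updated")
  } else {
    s <- as.data.frame(bundle)
    check_valueset_table(s)
    head_labels <- c("original", "updated")
  }
  cell <- function(m, lo, hi) {
    sprintf("%s (%s \u2014 %s)", fmt2(m), fmt2(lo), fmt2(hi))
  }
  star <- if (!is.null(s$significant)) ifelse(s$significant, " *", "")
          else ""
  lines <- sprintf("%-4s %-22s %-22s %s%s", s$label,
                   cell(s$original_mean, s$original_lo, s$original_hi),
                   cell(s$updated_mean, s$updated_lo, s$updated_hi),
                   cell(s$diff_mean, s$diff_lo, s$diff_hi), star)
  c(sprintf("%-4s %-22s %-22s %s", "", head_labels[1], head_labels[2],
            "difference"),
    lines)
}
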