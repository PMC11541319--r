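#' @name data_io
#' @title Readers and writers for valuation data, demographic weights,
#'   posterior draws and value-set tables
#'
#' @description
#' The canonical long format for TTO valuation data is one row per
#' respondent x task with columns `respondent_id`, `sex`, `age` (years or
#' band), `state` (5-digit EQ-5D-3L code) and `value` (TTO value in
#' `[-1, 1]`).  Files with other headers are adapted through a
#' column-mapping list, never hard-coded parsers.  Demographic-weight
#' tables give one share per sex x age-band cell; printed tables are often
#' in percent, so percent vs proportion is auto-detected from the total
#' and the shares re-normalized to sum to exactly 1.
NULL

# ---- valuation datasets -----------------------------------------------------

#' Construct a TTO valuation dataset
#'
#' @param df Data frame with columns `respondent_id`, `sex`, `age_group`,
#'   `state`, `value`.
#' @param dialect Design dialect: `"sampled"` (each respondent values a
#'   subset of a larger design, as in the UK/US studies) or `"fixed"`
#'   (every respondent values the same task list, as in the Japanese
#'   study).
#' @param provenance Free-text origin tag carried through reports.
#' @return Object of class `tto_data`: the validated data frame plus a
#'   `censored` flag column (value equal to -1 within 1e-9, the censoring
#'   mass point of the TTO elicitation) and a `cell` column combining sex
#'   and age group.  Values below -1 are rejected; values above 1 are
#'   tolerated in memory because the latent-normal generative model is
#'   unbounded above (real data read through [read_tto_table()] enforce
#'   the elicitation bound of 1).
#' @export
tto_data <- function(df, dialect = c("sampled", "fixed"),
                     provenance = "unspecified") {
  dialect <- match.arg(dialect)
  need <- c("respondent_id", "sex", "age_group", "state", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$respondent_id <- as.character(df$respondent_id)
  df$sex <- normalize_sex(df$sex)
  df$age_group <- as.character(df$age_group)
  bad_ag <- !df$age_group %in% age_bands
  if (any(bad_ag)) {
    stop("unrecognized age group(s): ",
         paste(unique(df$age_group[bad_ag]), collapse = ", "), call. = FALSE)
  }
  df$state <- validate_state(df$state)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("non-finite TTO values", call. = FALSE)
  if (any(df$value < -1 - 1e-9)) {
    stop("TTO values below the censoring bound -1 are not allowed",
         call. = FALSE)
  }
  df$censored <- abs(df$value + 1) < 1e-9
  df$value[df$censored] <- -1
  df$cell <- cell_label(df$sex, df$age_group)
  out <- df[, c("respondent_id", "sex", "age_group", "cell",
                "state", "value", "censored")]
  rownames(out) <- NULL
  structure(out, class = c("tto_data", "data.frame"),
            dialect = dialect, provenance = provenance)
}

#' @export
print.tto_data <- function(x, ...) {
  cat(sprintf("TTO valuation dataset (%s): %d respondents, %d observations, %.1f%% censored\n",
              attr(x, "provenance"),
              length(unique(x$respondent_id)), nrow(x),
              100 * mean(x$censored)))
  invisible(x)
}

#' Number of respondents in a dataset
#' @param data A `tto_data` object.
#' @export
n_respondents <- function(data) length(unique(data$respondent_id))

# row-subset a tto_data, keeping class and dialect/provenance attributes
subset_tto <- function(data, keep) {
  out <- as.data.frame(data)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tto_data", "data.frame"),
            dialect = attr(data, "dialect"),
            provenance = attr(data, "provenance"))
}

#' Read a TTO valuation table
#'
#' @param path Delimited text file (CSV, or TSV when `sep = "\t"`) with a
#'   header row.
#' @param col_map Named list mapping the canonical column names
#'   `respondent_id`, `sex`, `age`, `state`, `value` to the file's header
#'   names; entries may be omitted when the file already uses the
#'   canonical name.  The `age` column may hold ages in years (recoded via
#'   [assign_age_group()]) or band labels directly.
#' @param sep Field separator, default `","`.
#' @param max_value Upper bound for observed values (default 1, full
#'   health); rows above it are rejected with their line numbers.  Real
#'   TTO data cannot exceed 1; set to `Inf` for model-generated data,
#'   whose latent-normal upper tail is unbounded.
#' @inheritParams tto_data
#' @return A [tto_data] object.
#' @export
read_tto_table <- function(path, col_map = NULL, sep = ",",
                           dialect = c("sampled", "fixed"),
                           provenance = basename(path), max_value = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read everything as character: a sex column of "F"s must not become
  # logical, and value parsing errors need line numbers
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  canon <- c("respondent_id", "sex", "age", "state", "value")
  map <- setNames(as.list(canon), canon)
  for (nm in names(col_map)) {
    if (!nm %in% canon) stop("unknown column-map entry: ", nm, call. = FALSE)
    map[[nm]] <- col_map[[nm]]
  }
  for (nm in canon) {
    if (!map[[nm]] %in% names(raw)) {
      stop("mandatory column '", nm, "' (file column '", map[[nm]],
           "') not found in ", path, call. = FALSE)
    }
  }
  df <- data.frame(respondent_id = raw[[map$respondent_id]],
                   sex = raw[[map$sex]],
                   age = raw[[map$age]],
                   state = as.character(raw[[map$state]]),
                   value = raw[[map$value]],
                   stringsAsFactors = FALSE)
  # line numbers: header is line 1
  line_of <- function(i) i + 1L
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))
    stop("unparseable TTO value at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  df$value <- val
  if (any(val > max_value + 1e-9)) {
    bad <- which(val > max_value + 1e-9)
    stop("TTO value above ", max_value, " at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  bad_state <- nchar(df$state) != 5L | grepl("[^123]", df$state)
  if (any(bad_state)) {
    bad <- which(bad_state)
    stop("malformed state code at line(s) ",
         paste(line_of(head(bad, 5L)), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  age_num <- suppressWarnings(as.numeric(df$age))
  if (!anyNA(age_num)) {
    df$age_group <- as.character(assign_age_group(age_num))
  } else {
    df$age_group <- as.character(df$age)
  }
  tto_data(df[, c("respondent_id", "sex", "age_group", "state", "value")],
           dialect = match.arg(dialect), provenance = provenance)
}

#' Write a TTO valuation table in the canonical long format
#'
#' @param data A [tto_data] object.
#' @param path Output CSV path.
#' @export
write_tto_table <- function(data, path) {
  stopifnot(inherits(data, "tto_data"))
  out <- data.frame(respondent_id = data$respondent_id,
                    sex = data$sex,
                    age = data$age_group,
                    state = data$state,
                    value = format(data$value, digits = 17, trim = TRUE,
                                   scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- demographic weights ----------------------------------------------------

#' Construct demographic weights
#'
#' Population shares over a set of demographic cells at a named time
#' point.  Shares are re-normalized to sum to exactly 1 so that rounding
#' in printed source tables cannot poison downstream weighted averages.
#'
#' @param shares Named numeric vector of non-negative shares, names being
#'   cell labels (see [demographic_cells()]).
#' @param label Time-point label, e.g. `"UK-1997"`.
#' @return Object of class `demographic_weights`: named numeric vector
#'   summing to 1, with a `label` attribute.
#' @export
demographic_weights <- function(shares, label = "weights") {
  if (is.null(names(shares)) || anyNA(names(shares))) {
    stop("shares must be a named vector of cell labels", call. = FALSE)
  }
  w <- setNames(as.numeric(shares), names(shares))
  if (any(w < 0) || any(!is.finite(w))) {
    stop("shares must be finite and non-negative", call. = FALSE)
  }
  w <- w / sum(w)
  structure(w, class = "demographic_weights", label = label)
}

#' @export
print.demographic_weights <- function(x, ...) {
  cat("Demographic weights [", attr(x, "label"), "]\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read a demographic-weights table
#'
#' @param path CSV with either columns `sex`, `age_group`, `share` or
#'   columns `cell`, `share`.
#' @param label Label for the weights; defaults to the file name.
#' @param scale `"auto"` detects percent vs proportion from the total
#'   (approximately 100 vs approximately 1, within 1 percent); use
#'   `"percent"` or `"proportion"` to override.
#' @return A [demographic_weights] object.
#' @export
read_weights <- function(path, label = sub("\\.[^.]*$", "", basename(path)),
                         scale = c("auto", "percent", "proportion")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sex", "age_group") %in% names(df))) {
    cells <- cell_label(normalize_sex(df$sex), df$age_group)
  } else if ("cell" %in% names(df)) {
    cells <- as.character(df$cell)
  } else {
    stop("weights table needs columns (sex, age_group) or cell", call. = FALSE)
  }
  if (!"share" %in% names(df)) {
    stop("weights table needs a 'share' column", call. = FALSE)
  }
  share <- as.numeric(df$share)
  tot <- sum(share)
  if (scale == "auto") {
    if (abs(tot - 100) <= 1) {
      share <- share / 100
    } else if (abs(tot - 1) <= 0.01) {
      # already proportions
    } else {
      stop("shares sum to ", format(tot),
           ": neither ~1 (proportions) nor ~100 (percent)", call. = FALSE)
    }
  } else if (scale == "percent") {
    share <- share / 100
  }
  demographic_weights(setNames(share, cells), label = label)
}

#' Bundled national demographic compositions
#'
#' Sex x age-band population shares for the United Kingdom, Japan and the
#' United States at the year of each country's original TTO valuation
#' study and in 2022, plus the (non-representative) compositions of the
#' survey samples themselves.
#'
#' @param label One of `"UK-1997"`, `"UK-2022"`, `"JPN-1998"`,
#'   `"JPN-2022"`, `"US-2002"`, `"US-2022"`, `"UK-sample"`,
#'   `"JPN-sample"`, `"US-sample"`.
#' @return A [demographic_weights] object over the 8 default cells.
#' @export
eq_weights <- function(label) {
  file <- file.path("weights", paste0(
    tolower(gsub("-", "_", label)), ".csv"))
  path <- system.file("extdata", file, package = "valuesetdrift")
  if (path == "" || !file.exists(path)) {
    stop("no bundled weights named '", label, "'", call. = FALSE)
  }
  read_weights(path, label = label)
}

# ---- value-set summary tables ----------------------------------------------

valueset_cols <- c("label",
                   "original_mean", "original_lo", "original_hi",
                   "updated_mean", "updated_lo", "updated_hi",
                   "diff_mean", "diff_lo", "diff_hi")

check_valueset_table <- function(x) {
  miss <- setdiff(valueset_cols, names(x))
  if (length(miss)) {
    stop("value-set summary lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (grp in c("original", "updated", "diff")) {
    lo <- x[[paste0(grp, "_lo")]]; hi <- x[[paste0(grp, "_hi")]]
    if (any(lo > hi + 1e-12)) {
      stop("inverted credible interval (lo > hi) in ", grp, " columns",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Write a value-set comparison table
#'
#' @param summary A value-set summary data frame (see
#'   [summarize_valuesets()]) with one row per decrement label and
#'   columns `label`, `{original,updated,diff}_{mean,lo,hi}`.
#' @param path Output CSV path.  Values are written at full double
#'   precision so `read_valueset(write_valueset(x))` round-trips to
#'   1e-12.
#' @export
write_valueset <- function(summary, path) {
  summary <- as.data.frame(summary)
  check_valueset_table(summary)
  out <- summary[, valueset_cols, drop = FALSE]
  for (nm in valueset_cols[-1]) {
    out[[nm]] <- format(out[[nm]], digits = 17, trim = TRUE,
                        scientific = TRUE)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_valueset
#' @export
read_valueset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(label = "character"))
  if (nrow(x)) check_valueset_table(x)
  x
}

# ---- posterior draws flat table --------------------------------------------

#' Write posterior draws as a flat table
#'
#' One row per (chain, draw, parameter), so any downstream tool can
#' consume the draws without package-specific containers.
#'
#' @param fit A `tobit_fit` object (see [fit_tobit()]).
#' @param path Output CSV path.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "tobit_fit"))
  pieces <- lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]]
    data.frame(chain = ch,
               draw = rep(seq_len(nrow(m)), times = ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  flat <- do.call(rbind, pieces)
  flat$value <- format(flat$value, digits = 17, trim = TRUE,
                       scientific = TRUE)
  write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path Flat draws CSV.
#' @return List of per-chain draw matrices (draws x parameters).
#' @export
read_draws <- function(path) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "draw", "parameter", "value")
  miss <- setdiff(need, names(flat))
  if (length(miss)) {
    stop("draws table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pars <- unique(flat$parameter)
  lapply(sort(unique(flat$chain)), function(ch) {
    sub <- flat[flat$chain == ch, ]
    m <- matrix(NA_real_, nrow = max(sub$draw), ncol = length(pars),
                dimnames = list(NULL, pars))
    for (p in pars) {
      v <- sub[sub$parameter == p, ]
      m[v$draw, p] <- v$value
    }
    m
  })
}
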