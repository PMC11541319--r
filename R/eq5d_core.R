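#' @name eq5d_core
#' @title EQ-5D-3L health-state coding utilities
#'
#' @description
#' An EQ-5D-3L health state is a profile over five dimensions -- mobility
#' (MO), self-care (SC), usual activities (UA), pain/discomfort (PD) and
#' anxiety/depression (AD) -- each at level 1 (no problems), 2 (some
#' problems) or 3 (extreme problems).  States are written as 5-digit codes
#' in the order MO, SC, UA, PD, AD, e.g. `"21321"`; there are 3^5 = 243
#' states.  Regression models for value sets use a dummy coding with one
#' indicator per dimension-level beyond level 1, giving ten indicators
#' `MO2, MO3, SC2, SC3, UA2, UA3, PD2, PD3, AD2, AD3`.
NULL

#' EQ-5D-3L dimension abbreviations, in state-code order
#' @export
eq5d_dimensions <- c("MO", "SC", "UA", "PD", "AD")

#' Labels of the ten dimension-level decrements
#'
#' @return Character vector `c("MO2","MO3",...,"AD2","AD3")`, the order used
#'   for regression coefficients throughout the package.
#' @export
decrement_labels <- function() {
  as.vector(t(outer(eq5d_dimensions, c("2", "3"), paste0)))
}

#' The four adult age bands used for demographic cells
#' @export
age_bands <- c("18-34", "35-54", "55-74", "75+")

validate_state <- function(code) {
  code <- as.character(code)
  bad <- nchar(code) != 5L | grepl("[^123]", code)
  if (any(bad)) {
    stop("invalid EQ-5D-3L state code(s): ",
         paste(unique(code[bad]), collapse = ", "),
         " (expected 5 digits, each in 1-3)", call. = FALSE)
  }
  code
}

state_levels <- function(code) {
  code <- validate_state(code)
  m <- matrix(as.integer(unlist(strsplit(code, "", fixed = TRUE))),
              ncol = 5L, byrow = TRUE)
  colnames(m) <- eq5d_dimensions
  m
}

#' Dummy-code EQ-5D-3L states
#'
#' Maps each state to the ten level-2/level-3 indicators used as regressors:
#' for dimension `d`, `d2 = 1` iff the dimension is at level 2 and `d3 = 1`
#' iff at level 3; level 1 contributes no indicator.
#'
#' @param code Character vector of 5-digit state codes.
#' @return A numeric matrix with one row per code and columns
#'   [decrement_labels()].  For a single code, a named vector.
#' @examples
#' encode_state("21321")
#' @export
encode_state <- function(code) {
  lv <- state_levels(code)
  out <- matrix(0, nrow = nrow(lv), ncol = 10L,
                dimnames = list(rownames(lv), decrement_labels()))
  for (d in seq_len(5L)) {
    out[, 2L * d - 1L] <- as.numeric(lv[, d] == 2L)
    out[, 2L * d]      <- as.numeric(lv[, d] == 3L)
  }
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Misery index of EQ-5D-3L states
#'
#' The misery index is the sum of the five dimension levels, a crude
#' severity score ranging from 5 (full health, `"11111"`) to 15
#' (`"33333"`).  It is used by the respondent quality filters.
#'
#' @inheritParams encode_state
#' @return Integer vector in `[5, 15]`.
#' @export
misery_index <- function(code) {
  as.integer(rowSums(state_levels(code)))
}

#' All 243 EQ-5D-3L state codes
#'
#' @return Character vector of the 243 codes, sorted.
#' @export
all_eq5d_states <- function() {
  g <- expand.grid(AD = 1:3, PD = 1:3, UA = 1:3, SC = 1:3, MO = 1:3)
  sort(paste0(g$MO, g$SC, g$UA, g$PD, g$AD))
}

#' Assign adult ages to the model's age bands
#'
#' @param age_years Integer vector of ages in years; all must be >= 18
#'   (adult valuation samples only).
#' @return Factor with levels [age_bands]: 18-34 for ages 18..34, 35-54,
#'   55-74, and 75+ for ages 75 and above.
#' @examples
#' assign_age_group(c(34, 35, 90))
#' @export
assign_age_group <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (any(!is.finite(age_years)) || any(age_years < 18)) {
    stop("ages must be >= 18 (adult valuation samples only)", call. = FALSE)
  }
  cut(age_years, breaks = c(18, 35, 55, 75, Inf), labels = age_bands,
      right = FALSE)
}

#' Demographic cells (sex x age band)
#'
#' The default grid crosses sex (Male, Female) with the four age bands,
#' giving G = 8 cells.  Downstream machinery accepts any finite set of
#' labelled cells; these labels are just the canonical default.
#'
#' @param sexes Character vector of sex labels.
#' @param age_groups Character vector of age-band labels.
#' @return Character vector of cell labels, `"<sex> <band>"`, sex-major.
#' @export
demographic_cells <- function(sexes = c("Male", "Female"),
                              age_groups = age_bands) {
  as.vector(t(outer(sexes, age_groups, paste)))
}

#' @rdname demographic_cells
#' @param sex,age_group Vectors recycled against each other.
#' @export
cell_label <- function(sex, age_group) {
  paste(as.character(sex), as.character(age_group))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("m", "male", "1"), "Male",
         ifelse(x %in% c("f", "female", "2"), "Female", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized sex label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
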