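#' Round half away from zero
#'
#' Commercial rounding to match how epidemiological tables are usually
#' printed (`round()` in R rounds half to even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

#' Percentage of a count over a denominator, printed-table style
#' @noRd
pct_of <- function(n, denom, digits = 1) {
  out <- round_half_up(100 * n / denom, digits)
  out[!is.finite(out)] <- NA_real_
  out
}

#' @noRd
as_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

#' Age in completed years at a reference date
#' @noRd
age_at <- function(birth_year_month, at) {
  birth <- as_date_safe(birth_year_month)
  at <- as_date_safe(at)
  yrs <- as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y"))
  before_birthday <- format(at, "%m%d") < format(birth, "%m%d")
  as.integer(yrs - as.integer(before_birthday))
}

#' Normalize an ICD-10 code: uppercase, trimmed, dot removed
#' @noRd
normalize_icd10 <- function(code) {
  gsub("\\.", "", toupper(trimws(code)))
}

#' Does an ICD-10 code match any code/prefix in a set? (prefix semantics)
#' @noRd
icd10_in_set <- function(codes, set) {
  codes <- normalize_icd10(codes)
  set <- normalize_icd10(set)
  vapply(codes, function(cd) {
    any(vapply(set, function(s) startsWith(cd, s), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(glue::glue(
      "{what}: missing required column{if (length(missing) > 1) 's' else ''}: ",
      "{paste(missing, collapse = ', ')}"
    ))
  }
  invisible(df)
}
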