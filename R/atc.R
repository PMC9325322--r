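# ATC code grammar and pattern matching.
#
# A full ATC code has the shape L DD L L DD (e.g. B01AA03 = warfarin).
# Knowledge-base rules may use either a full code or a prefix wildcard
# ("J01FA*" = all macrolides), optionally with an exclusion list
# ("J01FA*!J01FA10" = macrolides except azithromycin).

FULL_ATC_RE <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
# any valid ATC level: L, LDD, LDDL, LDDLL, LDDLLDD
ATC_PREFIX_RE <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

#' Normalize an ATC code or pattern
#'
#' Uppercases and strips whitespace. Matching everywhere in the package is
#' case-insensitive and whitespace-tolerant.
#'
#' @param x character vector of ATC codes or patterns
#' @return normalized character vector
#' @export
normalize_atc <- function(x) {
  toupper(gsub("[[:space:]]", "", x))
}

#' Is this a valid full 7-character ATC code?
#' @param x character vector
#' @return logical vector
#' @export
is_full_atc <- function(x) {
  grepl(FULL_ATC_RE, normalize_atc(x))
}

#' Parse an ATC pattern into prefix + exclusions
#'
#' Patterns: a full code ("B01AA03"), a prefix wildcard ("J01FA*"), either
#' optionally followed by "!" and a comma-separated exclusion list of full
#' codes ("J01FA*!J01FA10").
#'
#' @noRd
parse_atc_pattern <- function(pattern) {
  pattern <- normalize_atc(pattern)
  parts <- strsplit(pattern, "!", fixed = TRUE)[[1]]
  if (length(parts) > 2 || nchar(parts[1]) == 0) {
    abort(glue::glue("malformed ATC pattern: '{pattern}'"))
  }
  body <- parts[1]
  wildcard <- endsWith(body, "*")
  prefix <- sub("\\*$", "", body)
  if (wildcard) {
    if (!grepl(ATC_PREFIX_RE, prefix)) {
      abort(glue::glue("malformed ATC pattern: '{pattern}' (bad prefix '{prefix}')"))
    }
  } else if (!grepl(FULL_ATC_RE, prefix)) {
    abort(glue::glue(
      "malformed ATC pattern: '{pattern}' (not a full code; use a trailing '*' for prefixes)"
    ))
  }
  exclusions <- character(0)
  if (length(parts) == 2) {
    exclusions <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    bad <- exclusions[!grepl(FULL_ATC_RE, exclusions)]
    if (length(bad) > 0) {
      abort(glue::glue(
        "malformed ATC pattern: '{pattern}' (exclusions must be full codes: ",
        "{paste(bad, collapse = ', ')})"
      ))
    }
  }
  list(prefix = prefix, wildcard = wildcard, exclusions = exclusions)
}

#' Match a full ATC code against a pattern
#'
#' A code matches an exact pattern by string equality and a wildcard pattern
#' by prefix, unless it appears in the pattern's exclusion list. Matching is
#' case-insensitive and whitespace-stripped.
#'
#' @param code character vector of full 7-character ATC codes
#' @param pattern a single ATC pattern (see [normalize_atc()] for grammar):
#'   full code, or prefix ending in `*`, optionally with `!`-separated
#'   exclusion list, e.g. `"J01FA*!J01FA10"`
#' @return logical vector, one element per code
#' @examples
#' match_atc("J01FA09", "J01FA*!J01FA10") # clarithromycin: TRUE
#' match_atc("J01FA10", "J01FA*!J01FA10") # azithromycin excluded: FALSE
#' @export
match_atc <- function(code, pattern) {
  stopifnot(length(pattern) == 1)
  code <- normalize_atc(code)
  bad <- code[!is_full_atc(code)]
  if (length(bad) > 0) {
    abort(glue::glue("match_atc: not full ATC codes: {paste(unique(bad), collapse = ', ')}"))
  }
  p <- parse_atc_pattern(pattern)
  hit <- if (p$wildcard) startsWith(code, p$prefix) else code == p$prefix
  hit & !(code %in% p$exclusions)
}

#' Match codes against any of several patterns
#' @noRd
match_any_atc <- function(code, patterns) {
  if (length(patterns) == 0) return(rep(FALSE, length(code)))
  Reduce(`|`, lapply(patterns, function(p) match_atc(code, p)))
}
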