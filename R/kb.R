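# Knowledge base of interaction rules, Beers conditions and code sets.
#
# The shipped mini-KB (inst/extdata/kb.json) is a curated starter set for
# oral-anticoagulant bleeding-risk screening. The loader validates every
# rule; invalid rules are rejected (not fatal) and reported, so a partially
# corrupt user-supplied KB still loads what it can.

SEVERITY_LEVELS <- c("minor", "moderate", "major")
MECHANISMS <- c("PD", "PK_CYP2C9_2C19", "PK_CYP3A4", "PK_PGP", "PK_CYP3A4_PGP")
MICROMEDEX_LEVELS <- c("contraindicated", "major", "moderate")

#' Harmonize Theriaque and Micromedex interaction severities
#'
#' Maps the two vendor scales onto a common three-class scale: Theriaque
#' levels 1 ("contraindicated") and 2 ("not recommended") and Micromedex
#' "contraindicated"/"major" are `major`; Theriaque 3 ("use with caution")
#' and Micromedex "moderate" are `moderate`; Theriaque 4 ("to take into
#' account") is `minor`. When both sources are present the more severe
#' harmonized class wins (pharmacovigilance-conservative conflict rule).
#'
#' @param theriaque integer vector in 1:4, or `NA` when the source is silent
#' @param micromedex character vector in `c("contraindicated", "major",
#'   "moderate")`, or `NA`
#' @return character vector: `"major"`, `"moderate"` or `"minor"`
#' @examples
#' harmonize_severity(3, NA)        # "moderate"
#' harmonize_severity(4, "major")   # "major": most severe source wins
#' @export
harmonize_severity <- function(theriaque, micromedex) {
  n <- max(length(theriaque), length(micromedex))
  theriaque <- rep_len(as.integer(theriaque), n)
  micromedex <- rep_len(as.character(micromedex), n)
  if (any(!is.na(theriaque) & !(theriaque %in% 1:4))) {
    abort("harmonize_severity: Theriaque level must be in 1:4")
  }
  if (any(!is.na(micromedex) & !(micromedex %in% MICROMEDEX_LEVELS))) {
    abort(glue::glue(
      "harmonize_severity: Micromedex level must be one of ",
      "{paste(MICROMEDEX_LEVELS, collapse = ', ')}"
    ))
  }
  if (any(is.na(theriaque) & is.na(micromedex))) {
    abort("harmonize_severity: at least one source severity must be present")
  }
  th_rank <- dplyr::case_when(
    theriaque %in% c(1L, 2L) ~ 3L,
    theriaque == 3L ~ 2L,
    theriaque == 4L ~ 1L,
    TRUE ~ 0L
  )
  mm_rank <- dplyr::case_when(
    micromedex %in% c("contraindicated", "major") ~ 3L,
    micromedex == "moderate" ~ 2L,
    TRUE ~ 0L
  )
  SEVERITY_LEVELS[pmax(th_rank, mm_rank)]
}

#' @noRd
canonical_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' Load a knowledge base from a JSON file
#'
#' Reads, validates and freezes a knowledge base: interaction rules (ATC
#' pattern pairs with dual-source severities and a mechanism class), Beers
#' oral-anticoagulant conditions, and the ICD-10/ATC code sets used by the
#' bleeding-event phenotype. Rules that fail validation (malformed ATC
#' pattern, no severity from either source, unknown mechanism, duplicate
#' unordered pair) are dropped and listed in the `rejected` component.
#'
#' @param path path to a KB JSON file; defaults to the shipped mini-KB
#' @return an object of class `pimddi_kb`: a list with tibbles
#'   `interactions` and `pim_rules`, a named list `code_sets`, a `rejected`
#'   tibble (reason per dropped rule) and `meta` provenance fields
#' @export
load_kb <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kb.json", package = "pimddi")
  }
  if (!file.exists(path)) abort(glue::glue("KB file not found: {path}"))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$schema_version)) abort("KB file does not declare schema_version")

  rejected <- list()
  rules <- list()
  seen <- character(0)
  for (i in seq_along(raw$interactions)) {
    r <- raw$interactions[[i]]
    reason <- NULL
    a <- normalize_atc(r$drug_a %||% "")
    b <- normalize_atc(r$drug_b %||% "")
    ok_patterns <- tryCatch(
      {
        parse_atc_pattern(a)
        parse_atc_pattern(b)
        TRUE
      },
      error = function(e) FALSE
    )
    th <- r$severity_theriaque
    mm <- r$severity_micromedex
    if (!ok_patterns) {
      reason <- "invalid ATC pattern"
    } else if (is.null(th) && is.null(mm)) {
      reason <- "severity absent from both sources"
    } else if (!is.null(th) && !(th %in% 1:4)) {
      reason <- "Theriaque severity outside 1:4"
    } else if (!is.null(mm) && !(mm %in% MICROMEDEX_LEVELS)) {
      reason <- "unknown Micromedex severity"
    } else if (!((r$mechanism %||% "") %in% MECHANISMS)) {
      reason <- "unknown mechanism"
    } else if (canonical_pair_key(a, b) %in% seen) {
      reason <- "duplicate unordered pair"
    }
    if (!is.null(reason)) {
      rejected[[length(rejected) + 1]] <- tibble(
        index = i, drug_a = as.character(r$drug_a %||% NA),
        drug_b = as.character(r$drug_b %||% NA), reason = reason
      )
      next
    }
    seen <- c(seen, canonical_pair_key(a, b))
    rules[[length(rules) + 1]] <- tibble(
      drug_a_pattern = a,
      drug_b_pattern = b,
      severity_theriaque = if (is.null(th)) NA_integer_ else as.integer(th),
      severity_micromedex = if (is.null(mm)) NA_character_ else as.character(mm),
      mechanism = as.character(r$mechanism),
      bleeding_risk = isTRUE(r$bleeding_risk),
      heparin_switch = isTRUE(r$heparin_switch),
      source = as.character(r$source %||% "unspecified")
    )
  }
  interactions <- bind_rows(rules)
  interactions$severity <- harmonize_severity(
    interactions$severity_theriaque, interactions$severity_micromedex
  )

  pim_rules <- purrr::map_dfr(raw$pim_rules, function(r) {
    has_any <- !is.null(r$min_age_alone) || !is.null(r$min_age_with_renal) ||
      length(r$partner_patterns %||% list()) > 0
    if (!has_any) abort("PIM rule with no condition (no age threshold, no partner set)")
    tibble(
      anticoag_atc = normalize_atc(r$anticoag_atc),
      min_age_alone = if (is.null(r$min_age_alone)) NA_integer_ else as.integer(r$min_age_alone),
      min_age_with_renal = if (is.null(r$min_age_with_renal)) NA_integer_ else as.integer(r$min_age_with_renal),
      partner_patterns = list(normalize_atc(unlist(r$partner_patterns %||% character(0))))
    )
  })

  code_sets <- lapply(raw$code_sets, function(x) as.character(unlist(x)))
  required_sets <- c("bleeding_icd10", "antidote_atc", "anticoagulant_atc",
                     "renal_impairment_icd10")
  missing_sets <- setdiff(required_sets, names(code_sets))
  if (length(missing_sets) > 0) {
    abort(glue::glue("KB missing code set(s): {paste(missing_sets, collapse = ', ')}"))
  }
  if (any(lengths(code_sets) == 0)) abort("KB code sets must be non-empty")

  structure(
    list(
      interactions = interactions,
      pim_rules = pim_rules,
      code_sets = code_sets,
      rejected = if (length(rejected)) bind_rows(rejected) else
        tibble(index = integer(), drug_a = character(), drug_b = character(),
               reason = character()),
      meta = list(
        schema_version = raw$schema_version,
        name = raw$name %||% basename(path),
        path = path,
        loaded_at = Sys.time()
      )
    ),
    class = "pimddi_kb"
  )
}

#' @export
print.pimddi_kb <- function(x, ...) {
  cat("<pimddi knowledge base>", x$meta$name, "\n")
  cat("  interactions:", nrow(x$interactions),
      sprintf("(%d rejected)", nrow(x$rejected)), "\n")
  cat("  PIM rules:   ", nrow(x$pim_rules), "\n")
  cat("  code sets:   ",
      paste(sprintf("%s[%d]", names(x$code_sets), lengths(x$code_sets)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Validate a knowledge base file
#'
#' Loads the file and reports every rejected rule; useful before swapping
#' in a licensed interaction database.
#'
#' @inheritParams load_kb
#' @return tibble of rejected rules with reasons (zero rows = clean)
#' @export
kb_validate <- function(path = NULL) {
  load_kb(path)$rejected
}

#' @noRd
anticoag_molecule <- function(atc) {
  dplyr::recode(normalize_atc(atc),
    "B01AA03" = "warfarin", "B01AE07" = "dabigatran",
    "B01AF01" = "rivaroxaban", "B01AF02" = "apixaban",
    .default = NA_character_
  )
}
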