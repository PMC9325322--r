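# Readers and writers for the linked-cohort input tables.
#
# Five CSV dialects (UTF-8, comma-separated, header row):
#   patients.csv        patient_id, sex, birth_year_month, index_admission_date
#                       [, renal_override]
#   dispensing.csv      patient_id, atc_code, dispense_date [, supply_days]
#   administrations.csv patient_id, atc_code, admin_date
#   stays.csv           patient_id, admission_date, discharge_date, stay_type,
#                       icd10_codes (semicolon-joined, ":P"/":A" position suffix)
#   labs.csv            patient_id, date, analyte, value
#
# Reading validates every record; rows violating an invariant are dropped
# and reported (see validation_report()), a missing column is a hard error.

TABLE_KINDS <- c("patients", "dispensing", "administrations", "stays", "labs")

table_schema <- function(kind) {
  switch(kind,
    patients = list(
      required = c("patient_id", "sex", "birth_year_month", "index_admission_date"),
      optional = "renal_override"
    ),
    dispensing = list(
      required = c("patient_id", "atc_code", "dispense_date"),
      optional = "supply_days"
    ),
    administrations = list(required = c("patient_id", "atc_code", "admin_date"),
                           optional = character(0)),
    stays = list(
      required = c("patient_id", "admission_date", "discharge_date",
                   "stay_type", "icd10_codes"),
      optional = character(0)
    ),
    labs = list(required = c("patient_id", "date", "analyte", "value"),
                optional = character(0)),
    abort(glue::glue("unknown table kind '{kind}'; expected one of: ",
                     "{paste(TABLE_KINDS, collapse = ', ')}"))
  )
}

ICD10_ENTRY_RE <- "^[A-Z][0-9]{2}[0-9A-Z.]*:(P|A)$"

#' Read and validate a cohort input table
#'
#' Parses one of the five CSV dialects (`patients`, `dispensing`,
#' `administrations`, `stays`, `labs`), enforcing each record type's
#' invariants. Invalid records are dropped and collected in a validation
#' report attached as the `"validation"` attribute (see
#' [validation_report()]); a missing required column is an error.
#'
#' @param path path to the CSV file
#' @param kind table kind, one of `"patients"`, `"dispensing"`,
#'   `"administrations"`, `"stays"`, `"labs"`
#' @return a tibble of valid records with typed columns and a
#'   `"validation"` attribute listing rejected rows (CSV line numbers,
#'   header = line 1)
#' @export
read_oac_table <- function(path, kind = TABLE_KINDS) {
  kind <- arg_match(kind)
  if (!file.exists(path)) abort(glue::glue("file not found: {path}"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  out <- validate_oac_table(raw, kind)
  out
}

#' Validate an in-memory cohort table
#'
#' Same checks as [read_oac_table()] for a data frame already in memory
#' (e.g. built programmatically). Columns may be character (parsed) or
#' already typed.
#'
#' @param df data frame with the kind's columns
#' @inheritParams read_oac_table
#' @return validated tibble with a `"validation"` attribute
#' @export
validate_oac_table <- function(df, kind = TABLE_KINDS) {
  kind <- arg_match(kind)
  schema <- table_schema(kind)
  assert_columns(df, schema$required, glue::glue("{kind} table"))
  df <- as_tibble(df)
  n <- nrow(df)
  line <- seq_len(n) + 1L # CSV line numbers, header is line 1
  problems <- list()
  bad <- rep(FALSE, n)
  flag <- function(which, column, message) {
    if (any(which)) {
      problems[[length(problems) + 1]] <<- tibble(
        line = line[which], column = column, message = message
      )
      bad <<- bad | which
    }
  }

  parse_date_col <- function(col) {
    x <- df[[col]]
    parsed <- if (inherits(x, "Date")) x else as.Date(as.character(x), format = "%Y-%m-%d")
    flag(is.na(parsed) & !is.na(x), col, "unparseable date (expected YYYY-MM-DD)")
    flag(is.na(x), col, "missing value")
    parsed
  }

  if (kind == "patients") {
    sex <- toupper(trimws(as.character(df$sex)))
    flag(!(sex %in% c("M", "F")), "sex", "sex must be M or F")
    bym_chr <- as.character(df$birth_year_month)
    # accept YYYY-MM or YYYY-MM-DD; stored as first of month
    bym_chr <- ifelse(grepl("^[0-9]{4}-[0-9]{2}$", bym_chr),
                      paste0(bym_chr, "-01"), bym_chr)
    bym <- as.Date(bym_chr, format = "%Y-%m-%d")
    flag(is.na(bym), "birth_year_month", "unparseable month (expected YYYY-MM)")
    bym <- as.Date(format(bym, "%Y-%m-01"))
    idx <- parse_date_col("index_admission_date")
    ok <- !is.na(bym) & !is.na(idx)
    flag(ok & idx <= bym, "index_admission_date",
         "index admission must be strictly after birth month")
    age <- rep(NA_integer_, n)
    age[ok] <- age_at(bym[ok], idx[ok])
    flag(ok & age < 65, "birth_year_month",
         "age at index admission below 65 (cohort inclusion)")
    renal <- if ("renal_override" %in% names(df)) {
      as.logical(df$renal_override)
    } else {
      rep(NA, n)
    }
    out <- tibble(patient_id = as.character(df$patient_id), sex = sex,
                  birth_year_month = bym, index_admission_date = idx,
                  renal_override = renal)
  } else if (kind == "dispensing") {
    atc <- normalize_atc(as.character(df$atc_code))
    flag(!is_full_atc(atc), "atc_code", "not a full 7-character ATC code")
    d <- parse_date_col("dispense_date")
    supply <- if ("supply_days" %in% names(df)) {
      suppressWarnings(as.integer(df$supply_days))
    } else {
      rep(NA_integer_, n)
    }
    flag(!is.na(supply) & supply <= 0, "supply_days", "supply_days must be positive")
    out <- tibble(patient_id = as.character(df$patient_id), atc_code = atc,
                  dispense_date = d, supply_days = supply)
  } else if (kind == "administrations") {
    atc <- normalize_atc(as.character(df$atc_code))
    flag(!is_full_atc(atc), "atc_code", "not a full 7-character ATC code")
    d <- parse_date_col("admin_date")
    out <- tibble(patient_id = as.character(df$patient_id), atc_code = atc,
                  admin_date = d)
  } else if (kind == "stays") {
    adm <- parse_date_col("admission_date")
    dis <- parse_date_col("discharge_date")
    ok <- !is.na(adm) & !is.na(dis)
    flag(ok & dis < adm, "discharge_date", "discharge before admission")
    flag(ok & dis == adm, "discharge_date",
         "infra-day stay (length of stay must be >= 1 day)")
    st <- tolower(trimws(as.character(df$stay_type)))
    flag(!(st %in% c("medicine", "surgery")), "stay_type",
         "stay_type must be medicine or surgery")
    codes <- as.character(df$icd10_codes)
    codes_ok <- vapply(codes, function(s) {
      if (is.na(s) || s == "") return(TRUE) # a stay may carry no diagnosis
      entries <- strsplit(s, ";", fixed = TRUE)[[1]]
      all(grepl(ICD10_ENTRY_RE, normalize_icd10_entries(entries)))
    }, logical(1), USE.NAMES = FALSE)
    flag(!codes_ok, "icd10_codes",
         "entries must be ICD-10 codes with :P or :A position suffix")
    out <- tibble(patient_id = as.character(df$patient_id),
                  admission_date = adm, discharge_date = dis,
                  stay_type = st, icd10_codes = codes)
  } else { # labs
    d <- parse_date_col("date")
    analyte <- trimws(as.character(df$analyte))
    analyte <- ifelse(toupper(analyte) == "INR", "INR",
                      ifelse(tolower(analyte) == "hemoglobin", "hemoglobin", analyte))
    flag(!(analyte %in% c("INR", "hemoglobin")), "analyte",
         "analyte must be INR or hemoglobin")
    val <- suppressWarnings(as.numeric(df$value))
    flag(is.na(val), "value", "unparseable numeric value")
    flag(!is.na(val) & val <= 0, "value", "value must be positive")
    implausible <- !is.na(val) &
      ((analyte == "INR" & val > 20) | (analyte == "hemoglobin" & val > 25))
    if (any(implausible)) {
      warn(glue::glue("{sum(implausible)} lab value(s) outside plausibility bounds ",
                      "(INR <= 20, hemoglobin <= 25 g/dL) dropped"))
    }
    flag(implausible, "value", "value outside plausibility bounds")
    out <- tibble(patient_id = as.character(df$patient_id), date = d,
                  analyte = analyte, value = val)
  }

  report <- if (length(problems)) {
    arrange(bind_rows(problems), .data$line)
  } else {
    tibble(line = integer(), column = character(), message = character())
  }
  out <- out[!bad, , drop = FALSE]
  attr(out, "validation") <- report
  attr(out, "kind") <- kind
  out
}

#' @noRd
normalize_icd10_entries <- function(entries) {
  entries <- toupper(trimws(entries))
  # position suffix defaults to associated when absent
  ifelse(grepl(":", entries, fixed = TRUE), entries, paste0(entries, ":A"))
}

#' Retrieve the validation report of a loaded table
#'
#' @param x a tibble returned by [read_oac_table()] or [validate_oac_table()]
#' @return tibble with columns `line`, `column`, `message` (zero rows when
#'   every record parsed cleanly)
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation")
  if (is.null(rep)) {
    tibble(line = integer(), column = character(), message = character())
  } else {
    rep
  }
}

#' Write a cohort table in its canonical CSV dialect
#'
#' Inverse of [read_oac_table()]: writing then reading reproduces the
#' records exactly.
#'
#' @param x validated tibble
#' @param path output CSV path
#' @inheritParams read_oac_table
#' @return `path`, invisibly
#' @export
write_oac_table <- function(x, path, kind = TABLE_KINDS) {
  kind <- arg_match(kind)
  schema <- table_schema(kind)
  cols <- intersect(c(schema$required, schema$optional), names(x))
  out <- x[, cols, drop = FALSE]
  if (kind == "patients") {
    out$birth_year_month <- format(as_date_safe(out$birth_year_month), "%Y-%m")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Long view of stay diagnoses
#'
#' Unpacks the semicolon-joined `icd10_codes` column into one row per
#' diagnosis with its position (`"P"` principal, `"A"` associated). Codes
#' are normalized (uppercased, dots stripped).
#'
#' @param stays validated stays tibble
#' @return tibble: `patient_id`, `admission_date`, `discharge_date`,
#'   `stay_type`, `code`, `position`
#' @export
stay_diagnoses <- function(stays) {
  if (nrow(stays) == 0) {
    return(tibble(patient_id = character(), admission_date = as.Date(character()),
                  discharge_date = as.Date(character()), stay_type = character(),
                  code = character(), position = character()))
  }
  stays |>
    mutate(.entry = purrr::map(.data$icd10_codes, function(s) {
      if (is.na(s) || s == "") return(character(0))
      normalize_icd10_entries(strsplit(s, ";", fixed = TRUE)[[1]])
    })) |>
    select("patient_id", "admission_date", "discharge_date", "stay_type", ".entry") |>
    tidyr::unnest_longer(".entry") |>
    tidyr::separate_wider_delim(".entry", ":", names = c("code", "position")) |>
    mutate(code = normalize_icd10(.data$code))
}
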