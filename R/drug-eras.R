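# Drug-era construction: continuous exposure intervals per patient, drug
# and care setting, built from dispensing claims (primary care) and
# in-hospital administration records.

#' Merge overlapping or near-adjacent exposure intervals
#'
#' Collapses intervals for the same (patient, drug, setting) whenever the
#' gap between consecutive intervals is at most `gap_tolerance_days`
#' (`next start - current end <= tolerance`; intervals are closed on both
#' ends, so touching intervals always merge at tolerance 0). Idempotent.
#'
#' @param eras tibble with columns `patient_id`, `atc_code`, `start`,
#'   `end`, `setting`
#' @param gap_tolerance_days non-negative integer; maximal bridged gap
#' @return merged eras, sorted by patient, drug, setting, start
#' @export
merge_eras <- function(eras, gap_tolerance_days = 0) {
  if (gap_tolerance_days < 0) abort("gap_tolerance_days must be non-negative")
  if (nrow(eras) == 0) return(eras)
  eras |>
    arrange(.data$patient_id, .data$atc_code, .data$setting, .data$start, .data$end) |>
    group_by(.data$patient_id, .data$atc_code, .data$setting) |>
    mutate(
      .run = cumsum(
        as.numeric(.data$start) >
          lag(cummax(as.numeric(.data$end)), default = -Inf) + gap_tolerance_days
      )
    ) |>
    group_by(.data$patient_id, .data$atc_code, .data$setting, .data$.run) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("patient_id", "atc_code", "start", "end", "setting") |>
    arrange(.data$patient_id, .data$atc_code, .data$setting, .data$start)
}

#' Build drug eras from dispensing and administration records
#'
#' Primary-care eras cover `[dispense_date, dispense_date + supply_days]`
#' per dispensing (a record's own `supply_days` wins over the default);
#' hospital eras are maximal runs of administration dates. Within one
#' (patient, drug, setting), intervals separated by at most
#' `gap_tolerance_days` are merged.
#'
#' @param dispensings validated dispensing tibble (may be zero-row)
#' @param administrations validated administrations tibble (may be zero-row
#'   or `NULL`)
#' @param supply_days_default assumed coverage of a dispensing when the
#'   record carries none; 30 days by convention (monthly dispensing in
#'   French community pharmacy)
#' @param gap_tolerance_days maximal gap bridged when merging (default 0:
#'   only overlapping or touching intervals merge)
#' @return era tibble: `patient_id`, `atc_code`, `start`, `end`, `setting`
#'   (`"primary_care"` or `"hospital"`), non-overlapping within each
#'   (patient, drug, setting), sorted
#' @examples
#' d <- tibble::tibble(patient_id = "p1", atc_code = "B01AA03",
#'                     dispense_date = as.Date("2016-01-01") + c(0, 30),
#'                     supply_days = NA_integer_)
#' build_drug_eras(d) # one merged 60-day era
#' @export
build_drug_eras <- function(dispensings = NULL, administrations = NULL,
                            supply_days_default = 30, gap_tolerance_days = 0) {
  if (supply_days_default <= 0) abort("supply_days_default must be positive")
  if (gap_tolerance_days < 0) abort("gap_tolerance_days must be non-negative")
  empty <- tibble(patient_id = character(), atc_code = character(),
                  start = as.Date(character()), end = as.Date(character()),
                  setting = character())
  pc <- if (!is.null(dispensings) && nrow(dispensings) > 0) {
    supply <- dispensings$supply_days %||% rep(NA_integer_, nrow(dispensings))
    supply <- ifelse(is.na(supply), supply_days_default, supply)
    tibble(
      patient_id = dispensings$patient_id,
      atc_code = normalize_atc(dispensings$atc_code),
      start = as_date_safe(dispensings$dispense_date),
      end = as_date_safe(dispensings$dispense_date) + supply,
      setting = "primary_care"
    )
  } else {
    empty
  }
  hosp <- if (!is.null(administrations) && nrow(administrations) > 0) {
    tibble(
      patient_id = administrations$patient_id,
      atc_code = normalize_atc(administrations$atc_code),
      start = as_date_safe(administrations$admin_date),
      end = as_date_safe(administrations$admin_date),
      setting = "hospital"
    )
  } else {
    empty
  }
  merge_eras(bind_rows(pc, hosp), gap_tolerance_days)
}

#' Clip eras to a closed date window, dropping empty results
#' @noRd
clip_eras <- function(eras, window_start, window_end) {
  eras |>
    mutate(start = pmax(.data$start, window_start),
           end = pmin(.data$end, window_end)) |>
    filter(.data$start <= .data$end)
}
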