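# The frozen 12-patient worked example: a hand-verified micro-cohort
# exercising every rule branch (each Beers condition, each ADE criterion,
# each pathway label, one warfarin triple combination, the azithromycin
# exclusion, and both laboratory boundary cases).

#' Load the 12-patient worked example
#'
#' A tiny fixed cohort with hand-verifiable findings: every PIM rule,
#' every ADE criterion, every pathway label and a warfarin-amiodarone +
#' paracetamol triple combination appear at least once. The companion
#' expected-findings table is the frozen reference the pipeline must
#' reproduce exactly; [summarise_screen_patients()] puts a screening
#' result into the same shape for comparison.
#'
#' @return list: `tables` (validated patients/dispensing/administrations/
#'   stays/labs) and `expected` (one row per patient: exposure, PIM rule,
#'   DDI count and worst severity, PIM-DDI flag, ADE criterion, pathway)
#' @export
make_worked_example <- function() {
  dir <- system.file("extdata", "worked_example", package = "pimddi")
  kinds <- c("patients", "dispensing", "administrations", "stays", "labs")
  tables <- lapply(setNames(kinds, kinds), function(k) {
    read_oac_table(file.path(dir, paste0(k, ".csv")), k)
  })
  expected <- readr::read_csv(
    file.path(dir, "expected_findings.csv"),
    col_types = readr::cols(
      patient_id = "c", molecule = "c", pre_exposed = "l", pim = "l",
      pim_rule = "c", pim_partner = "c", n_ddi = "i", max_severity = "c",
      pim_ddi = "l", is_ade = "l", criteria = "c", pathway = "c"
    ),
    na = "NA", progress = FALSE
  ) |>
    mutate(criteria = dplyr::coalesce(.data$criteria, ""),
           criteria = if_else(is.na(.data$is_ade), NA_character_,
                              .data$criteria))
  list(tables = tables, expected = expected)
}

#' Per-patient findings summary of a screening result
#'
#' Collapses a [screen_cohort()] result to one row per patient in the
#' worked example's reference shape (primary-care setting findings).
#'
#' @param screen a `pimddi_screen` object
#' @return tibble matching the worked example's `expected` columns
#' @export
summarise_screen_patients <- function(screen) {
  pre <- screen$exposures |> filter(.data$setting == "primary_care")
  hosp <- screen$exposures |> filter(.data$setting == "hospital")
  molecule <- screen$exposures |>
    group_by(.data$patient_id) |>
    arrange(dplyr::desc(.data$setting == "primary_care")) |>
    summarise(molecule = first(.data$molecule), .groups = "drop")
  pim_pc <- screen$pim |>
    filter(.data$setting == "primary_care") |>
    group_by(.data$patient_id) |>
    slice(1) |>
    ungroup() |>
    select("patient_id", pim_rule = "triggered_rule",
           pim_partner = "partner_atc")
  ddi_pc <- screen$ddi |>
    filter(.data$setting == "primary_care") |>
    group_by(.data$patient_id) |>
    summarise(
      n_ddi = dplyr::n(),
      max_severity = SEVERITY_LEVELS[max(match(.data$severity, SEVERITY_LEVELS))],
      pim_ddi = any(.data$is_pim_ddi),
      .groups = "drop"
    )
  screen$pathway |>
    select("patient_id", "pathway", "pre_exposed") |>
    left_join(molecule, by = "patient_id") |>
    left_join(pim_pc, by = "patient_id") |>
    left_join(ddi_pc, by = "patient_id") |>
    left_join(screen$ade |> select("patient_id", "is_ade",
                                   criteria = "criteria_fired"),
              by = "patient_id") |>
    mutate(
      pim = !is.na(.data$pim_rule),
      n_ddi = dplyr::coalesce(.data$n_ddi, 0L),
      pim_ddi = dplyr::coalesce(.data$pim_ddi, FALSE),
      pathway = as.character(.data$pathway)
    ) |>
    select("patient_id", "molecule", "pre_exposed", "pim", "pim_rule",
           "pim_partner", "n_ddi", "max_severity", "pim_ddi", "is_ade",
           "criteria", "pathway") |>
    arrange(.data$patient_id)
}
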