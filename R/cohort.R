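# End-to-end screening pipeline: tables -> eras -> exposures -> PIM/DDI
# -> bleeding-ADE phenotype -> pathway -> modelling cohort.

# ICD-10 prefix sets for the regression covariates (dotless)
COVARIATE_ICD10 <- list(
  stroke = c("I63", "I64", "G45"),
  diabetes = c("E10", "E11", "E12", "E13", "E14"),
  liver = c("B18", "K70", "K71", "K72", "K73", "K74", "K76"),
  cancer = "C",
  hypertension = c("I10", "I11", "I12", "I13", "I15")
)

#' Run the full screening pipeline on a linked cohort
#'
#' Validates the five input tables, builds drug eras, detects
#' anticoagulant exposure per setting, classifies Beers PIM status,
#' screens for bleeding-risk DDI and PIM-DDI, phenotypes bleeding ADEs on
#' the index stay, labels treatment pathways, and assembles one modelling
#' row per primary-care-exposed patient. Patients with no anticoagulant
#' exposure in either setting are excluded (count reported in
#' `excluded_n` and via a message).
#'
#' @param tables named list with elements `patients`, `dispensing`,
#'   `administrations`, `stays`, `labs` (data frames; validated
#'   internally)
#' @param kb knowledge base from [load_kb()]
#' @param supply_days_default,gap_tolerance_days era construction
#'   parameters (see [build_drug_eras()])
#' @param window_days pre-admission window length (default 30)
#' @param hb_mode hemoglobin ADE criterion mode (see
#'   [detect_by_hemoglobin()])
#' @param include_heparin_switch see [detect_ddi()]
#' @param quiet suppress the exclusion message
#' @return object of class `pimddi_screen`: list with tibbles `eras`,
#'   `exposures`, `pim`, `ddi`, `ade`, `pathway`, `cohort`, the validated
#'   `tables`, and `excluded_n`
#' @export
screen_cohort <- function(tables, kb = load_kb(), supply_days_default = 30,
                          gap_tolerance_days = 0, window_days = 30,
                          hb_mode = c("threshold", "delta"),
                          include_heparin_switch = TRUE, quiet = FALSE) {
  hb_mode <- arg_match(hb_mode)
  needed <- c("patients", "dispensing", "administrations", "stays", "labs")
  missing <- setdiff(needed, names(tables))
  if (length(missing) > 0) {
    abort(glue::glue("tables list missing: {paste(missing, collapse = ', ')}"))
  }
  tables <- purrr::imap(tables[needed], validate_oac_table)

  eras <- build_drug_eras(tables$dispensing, tables$administrations,
                          supply_days_default, gap_tolerance_days)
  exposures <- detect_anticoag_exposure(tables$patients, tables$stays, eras,
                                        kb, window_days)
  exposed_ids <- unique(exposures$patient_id)
  excluded_n <- sum(!(tables$patients$patient_id %in% exposed_ids))
  if (excluded_n > 0 && !quiet) {
    inform(glue::glue(
      "{excluded_n} patient(s) with no anticoagulant exposure in either ",
      "setting excluded from the cohort"
    ))
  }
  patients <- tables$patients |> filter(.data$patient_id %in% exposed_ids)

  pim <- classify_pim(exposures, patients, tables$stays, eras, kb, window_days)
  ddi <- detect_ddi(patients, tables$stays, eras, kb,
                    window_days = window_days,
                    include_heparin_switch = include_heparin_switch)
  ddi <- flag_pim_ddi(ddi, pim, kb)

  pre_ids <- exposures$patient_id[exposures$setting == "primary_care"]
  ade <- detect_bleeding_ade(
    patients |> filter(.data$patient_id %in% pre_ids),
    tables$stays, tables$labs, tables$administrations, kb, hb_mode
  )
  pathway <- classify_pathway(patients, tables$stays, exposures, ade)
  cohort <- assemble_cohort_rows(patients, tables, eras, exposures, pim, ddi,
                                 ade, kb, window_days)

  structure(
    list(tables = tables, eras = eras, exposures = exposures, pim = pim,
         ddi = ddi, ade = ade, pathway = pathway, cohort = cohort,
         excluded_n = excluded_n, kb_name = kb$meta$name),
    class = "pimddi_screen"
  )
}

#' @export
print.pimddi_screen <- function(x, ...) {
  cat("<pimddi screening result>\n")
  cat("  patients (any exposure):", nrow(x$pathway),
      " excluded (no exposure):", x$excluded_n, "\n")
  cat("  modelling cohort (pre-admission exposure):", nrow(x$cohort), "\n")
  cat("  PIM findings:", nrow(x$pim), "  DDI events:", nrow(x$ddi),
      " (PIM-DDI:", sum(x$ddi$is_pim_ddi), ")\n")
  cat("  bleeding ADE:", sum(x$ade$is_ade), "of", nrow(x$ade), "\n")
  invisible(x)
}

#' One-row summary of a screening result
#' @param x a `pimddi_screen` object
#' @param ... unused
#' @return tibble of headline counts and prevalences (primary-care
#'   setting)
#' @export
glance.pimddi_screen <- function(x, ...) {
  pre_ids <- unique(x$exposures$patient_id[x$exposures$setting == "primary_care"])
  n_pre <- length(pre_ids)
  pim_ids <- unique(x$pim$patient_id[x$pim$setting == "primary_care"])
  ddi_pc <- x$ddi |> filter(.data$setting == "primary_care")
  tibble(
    n_patients = nrow(x$pathway),
    n_primary_care = n_pre,
    pct_pim = pct_of(length(pim_ids), n_pre),
    pct_ddi = pct_of(n_distinct(ddi_pc$patient_id), n_pre),
    pct_pim_ddi = pct_of(n_distinct(ddi_pc$patient_id[ddi_pc$is_pim_ddi]), n_pre),
    pct_ade = pct_of(sum(x$ade$is_ade), nrow(x$ade))
  )
}

#' Assemble the modelling cohort
#'
#' One row per patient exposed to an oral anticoagulant in primary care
#' in the pre-admission window: outcome (`ade`), demographics, look-back
#' comorbidity indicators, Charlson score, polymedication count, distinct
#' anticoagulant DDI pairs, PIM/DDI/PIM-DDI indicators, prior
#' hospitalization count, molecule indicators and exposure-duration
#' class (1: <=1 month, 2: 1-3, 3: 3-6, 4: >6 months of coverage in the
#' look-back year).
#'
#' @inheritParams detect_anticoag_exposure
#' @param tables validated table list
#' @param exposures,pim,ddi,ade upstream pipeline outputs
#' @return tibble, one row per cohort patient
#' @export
assemble_cohort_rows <- function(patients, tables, eras, exposures, pim, ddi,
                                 ade, kb = load_kb(), window_days = 30) {
  pre_ids <- unique(exposures$patient_id[exposures$setting == "primary_care"])
  base <- patients |>
    filter(.data$patient_id %in% pre_ids) |>
    mutate(age = age_at(.data$birth_year_month, .data$index_admission_date)) |>
    select("patient_id", "age", "sex", "index_admission_date")
  if (nrow(base) == 0) {
    return(tibble(patient_id = character()))
  }

  lookback_dx <- stay_diagnoses(tables$stays) |>
    inner_join(base |> select("patient_id", "index_admission_date"),
               by = "patient_id") |>
    filter(.data$admission_date >= .data$index_admission_date - 365,
           .data$admission_date <= .data$index_admission_date)
  prior_dx <- lookback_dx |> filter(.data$admission_date < .data$index_admission_date)

  flag_from_codes <- function(dx, set, name) {
    dx |>
      filter(icd10_in_set(.data$code, set)) |>
      distinct(.data$patient_id) |>
      mutate(!!name := TRUE)
  }
  comorb <- base |> select("patient_id")
  for (nm in names(COVARIATE_ICD10)) {
    comorb <- comorb |>
      left_join(flag_from_codes(lookback_dx, COVARIATE_ICD10[[nm]], nm),
                by = "patient_id")
  }
  comorb <- comorb |>
    left_join(flag_from_codes(prior_dx, kb$code_sets$bleeding_icd10,
                              "prev_bleed"), by = "patient_id") |>
    mutate(across(-"patient_id", ~ dplyr::coalesce(.x, FALSE)))

  renal <- renal_impairment_flags(
    patients |> filter(.data$patient_id %in% pre_ids), tables$stays, kb
  ) |>
    rename(renal = "renal_impairment")
  chs <- charlson_index(lookback_dx |> select("patient_id", "code")) |>
    right_join(base |> select("patient_id"), by = "patient_id") |>
    mutate(charlson = dplyr::coalesce(.data$charlson, 0L))

  windows <- setting_windows(patients, tables$stays, window_days)
  pre_eras <- eras_in_setting(eras, windows, "primary_care")
  polymed <- pre_eras |>
    group_by(.data$patient_id) |>
    summarise(polymedication = n_distinct(.data$atc_code), .groups = "drop")

  ddi_pc <- ddi |> filter(.data$setting == "primary_care")
  ddi_counts <- ddi_pc |>
    group_by(.data$patient_id) |>
    summarise(n_anticoag_ddi = dplyr::n(),
              ddi = TRUE,
              pim_ddi = any(.data$is_pim_ddi), .groups = "drop")
  pim_flag <- pim |>
    filter(.data$setting == "primary_care") |>
    distinct(.data$patient_id) |>
    mutate(pim = TRUE)

  prior_hosp <- tables$stays |>
    inner_join(base |> select("patient_id", "index_admission_date"),
               by = "patient_id") |>
    filter(.data$admission_date >= .data$index_admission_date - 365,
           .data$admission_date < .data$index_admission_date) |>
    count(.data$patient_id, name = "prior_hosp")

  molecules <- exposures |>
    filter(.data$setting == "primary_care", !is.na(.data$molecule)) |>
    distinct(.data$patient_id, .data$molecule) |>
    mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "molecule", values_from = "flag",
                       values_fill = FALSE)
  for (mol in c("warfarin", "rivaroxaban", "apixaban", "dabigatran")) {
    if (!mol %in% names(molecules)) molecules[[mol]] <- FALSE
  }

  anticoag_cov <- eras |>
    filter(.data$setting == "primary_care",
           .data$atc_code %in% kb$code_sets$anticoagulant_atc) |>
    inner_join(base |> select("patient_id", "index_admission_date"),
               by = "patient_id") |>
    mutate(start = pmax(.data$start, .data$index_admission_date - 365),
           end = pmin(.data$end, .data$index_admission_date)) |>
    filter(.data$start <= .data$end) |>
    group_by(.data$patient_id) |>
    summarise(cov_days = sum(as.numeric(.data$end - .data$start) + 1),
              .groups = "drop") |>
    mutate(exposure_duration_class = as.integer(
      cut(.data$cov_days, breaks = c(0, 31, 92, 183, Inf), labels = FALSE)
    ))

  ade_flag <- ade |> select("patient_id", ade = "is_ade")

  base |>
    select(-"index_admission_date") |>
    left_join(comorb, by = "patient_id") |>
    left_join(renal, by = "patient_id") |>
    left_join(chs, by = "patient_id") |>
    left_join(polymed, by = "patient_id") |>
    left_join(pim_flag, by = "patient_id") |>
    left_join(ddi_counts, by = "patient_id") |>
    left_join(prior_hosp, by = "patient_id") |>
    left_join(molecules, by = "patient_id") |>
    left_join(anticoag_cov |> select("patient_id", "exposure_duration_class"),
              by = "patient_id") |>
    left_join(ade_flag, by = "patient_id") |>
    mutate(
      across(c("pim", "ddi", "pim_ddi", "renal", "warfarin", "rivaroxaban",
               "apixaban", "dabigatran", "ade"),
             ~ dplyr::coalesce(.x, FALSE)),
      across(c("n_anticoag_ddi", "prior_hosp", "polymedication"),
             ~ dplyr::coalesce(.x, 0L)),
      exposure_duration_class = dplyr::coalesce(.data$exposure_duration_class, 1L)
    ) |>
    arrange(.data$patient_id)
}
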