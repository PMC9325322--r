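# Anticoagulant exposure and Beers PIM classification.
#
# Setting windows, per patient:
#   primary_care: the 30 days before the index admission,
#                 [index - window_days, index - 1] (closed)
#   hospital:     the index stay, [admission, discharge] (closed)

#' Per-patient setting windows
#' @noRd
setting_windows <- function(patients, stays, window_days = 30) {
  index_stays <- patients |>
    select("patient_id", "index_admission_date") |>
    left_join(
      stays |>
        select("patient_id", "admission_date", "discharge_date", "stay_type"),
      by = c("patient_id", index_admission_date = "admission_date")
    ) |>
    group_by(.data$patient_id) |>
    slice(1) |>
    ungroup()
  index_stays |>
    mutate(
      pre_start = .data$index_admission_date - window_days,
      pre_end = .data$index_admission_date - 1,
      hosp_start = .data$index_admission_date,
      hosp_end = .data$discharge_date
    )
}

#' @noRd
window_for <- function(windows, setting) {
  if (setting == "primary_care") {
    windows |>
      select("patient_id", window_start = "pre_start", window_end = "pre_end")
  } else {
    windows |>
      filter(!is.na(.data$hosp_end)) |>
      select("patient_id", window_start = "hosp_start", window_end = "hosp_end")
  }
}

#' Eras clipped to each patient's window for one setting
#' @noRd
eras_in_setting <- function(eras, windows, setting) {
  win <- window_for(windows, setting)
  eras |>
    filter(.data$setting == !!setting) |>
    inner_join(win, by = "patient_id") |>
    mutate(start = pmax(.data$start, .data$window_start),
           end = pmin(.data$end, .data$window_end)) |>
    filter(.data$start <= .data$end) |>
    select(-"window_start", -"window_end")
}

#' Detect oral anticoagulant exposure per setting
#'
#' A patient is exposed in primary care when an anticoagulant drug era
#' (from dispensing claims) intersects the 30-day pre-admission window,
#' and in hospital when an anticoagulant administration era intersects
#' the index stay.
#'
#' @param patients validated patients tibble
#' @param stays validated stays tibble (supplies the index stay bounds)
#' @param eras drug eras from [build_drug_eras()]
#' @param kb knowledge base from [load_kb()] (supplies the anticoagulant
#'   ATC set)
#' @param window_days length of the pre-admission window (default 30)
#' @return tibble: `patient_id`, `setting`, `atc_code`, `molecule`, one
#'   row per exposed (patient, setting, anticoagulant); zero rows when no
#'   one is exposed
#' @export
detect_anticoag_exposure <- function(patients, stays, eras, kb = load_kb(),
                                     window_days = 30) {
  windows <- setting_windows(patients, stays, window_days)
  anticoag <- kb$code_sets$anticoagulant_atc
  purrr::map_dfr(c("primary_care", "hospital"), function(s) {
    eras_in_setting(eras, windows, s) |>
      filter(.data$atc_code %in% anticoag) |>
      distinct(.data$patient_id, .data$setting, .data$atc_code)
  }) |>
    mutate(molecule = anticoag_molecule(.data$atc_code)) |>
    arrange(.data$patient_id, .data$setting, .data$atc_code)
}

#' Renal impairment flag per patient
#'
#' `renal_override` in the patients table wins when present (for cohorts
#' with eGFR-based flags); otherwise a patient is flagged when any stay in
#' the 1-year look-back (admissions within `[index - 365, index]`,
#' including the index stay) carries a diagnosis in the KB's
#' `renal_impairment_icd10` set (prefix matching).
#'
#' @inheritParams detect_anticoag_exposure
#' @return tibble: `patient_id`, `renal_impairment` (logical)
#' @export
renal_impairment_flags <- function(patients, stays, kb = load_kb()) {
  dx <- stay_diagnoses(stays) |>
    inner_join(patients |> select("patient_id", "index_admission_date"),
               by = "patient_id") |>
    filter(.data$admission_date >= .data$index_admission_date - 365,
           .data$admission_date <= .data$index_admission_date)
  coded <- dx |>
    filter(icd10_in_set(.data$code, kb$code_sets$renal_impairment_icd10)) |>
    distinct(.data$patient_id) |>
    mutate(renal_coded = TRUE)
  patients |>
    select("patient_id", "renal_override") |>
    left_join(coded, by = "patient_id") |>
    mutate(renal_impairment = dplyr::coalesce(.data$renal_override,
                                              .data$renal_coded, FALSE)) |>
    select("patient_id", "renal_impairment")
}

#' Overlapping Beers combo partners per (patient, setting, anticoagulant)
#' @noRd
combo_partners <- function(eras, windows, pim_rules) {
  empty <- tibble(patient_id = character(), setting = character(),
                  anticoag_atc = character(), partner_atc = character())
  combo_rules <- pim_rules |> filter(lengths(.data$partner_patterns) > 0)
  if (nrow(combo_rules) == 0) return(empty)
  out <- purrr::map_dfr(c("primary_care", "hospital"), function(s) {
    setting_eras <- eras_in_setting(eras, windows, s)
    if (nrow(setting_eras) == 0) return(NULL)
    purrr::pmap_dfr(
      list(combo_rules$anticoag_atc, combo_rules$partner_patterns),
      function(ac_atc, patterns) {
        ac <- setting_eras |> filter(.data$atc_code == ac_atc)
        if (nrow(ac) == 0) return(NULL)
        partners <- setting_eras |>
          filter(match_any_atc(.data$atc_code, patterns),
                 .data$atc_code != ac_atc)
        if (nrow(partners) == 0) return(NULL)
        partners |>
          inner_join(ac |> select("patient_id", ac_start = "start",
                                  ac_end = "end"),
                     by = "patient_id", relationship = "many-to-many") |>
          filter(.data$start <= .data$ac_end, .data$end >= .data$ac_start) |>
          group_by(.data$patient_id) |>
          summarise(partner_atc = min(.data$atc_code), .groups = "drop") |>
          mutate(setting = s, anticoag_atc = ac_atc)
      }
    )
  })
  if (nrow(out) == 0) return(empty)
  out |>
    group_by(.data$patient_id, .data$setting, .data$anticoag_atc) |>
    summarise(partner_atc = min(.data$partner_atc), .groups = "drop")
}

#' Classify potentially inappropriate anticoagulant use (Beers criteria)
#'
#' Applies the KB's Beers conditions to every detected anticoagulant
#' exposure: direct oral anticoagulants are PIM on age alone (>= 75 for
#' dabigatran and rivaroxaban) or at >= 65 with renal impairment (all
#' three DOACs); warfarin is PIM when a Beers partner drug era (amiodarone,
#' cotrimoxazole, ciprofloxacin, a macrolide other than azithromycin, or
#' an NSAID) overlaps the warfarin era within the setting window. The most
#' specific triggered rule is returned (age alone before age + renal).
#'
#' @param exposures output of [detect_anticoag_exposure()]
#' @inheritParams detect_anticoag_exposure
#' @return tibble of PIM findings: `patient_id`, `setting`, `anticoag_atc`,
#'   `molecule`, `triggered_rule` (`"age_ge_75"`, `"age_ge_65_renal"` or
#'   `"warfarin_combo"`), `partner_atc` (lowest-sorting overlapping Beers
#'   partner for combos, else `NA`), `age`, `renal_impairment`. Exposures
#'   meeting no condition produce no row.
#' @export
classify_pim <- function(exposures, patients, stays, eras, kb = load_kb(),
                         window_days = 30) {
  empty <- tibble(patient_id = character(), setting = character(),
                  anticoag_atc = character(), molecule = character(),
                  triggered_rule = character(), partner_atc = character(),
                  age = integer(), renal_impairment = logical())
  if (nrow(exposures) == 0) return(empty)
  windows <- setting_windows(patients, stays, window_days)
  renal <- renal_impairment_flags(patients, stays, kb)
  partners <- combo_partners(eras, windows, kb$pim_rules)
  findings <- exposures |>
    left_join(patients |> select("patient_id", "birth_year_month",
                                 "index_admission_date"),
              by = "patient_id") |>
    left_join(renal, by = "patient_id") |>
    mutate(age = age_at(.data$birth_year_month, .data$index_admission_date)) |>
    left_join(kb$pim_rules, by = c(atc_code = "anticoag_atc")) |>
    filter(!purrr::map_lgl(.data$partner_patterns, is.null)) |>
    left_join(partners,
              by = c("patient_id", "setting", atc_code = "anticoag_atc")) |>
    mutate(
      triggered_rule = case_when(
        !is.na(.data$min_age_alone) & .data$age >= .data$min_age_alone ~
          "age_ge_75",
        !is.na(.data$min_age_with_renal) &
          .data$age >= .data$min_age_with_renal & .data$renal_impairment ~
          "age_ge_65_renal",
        !is.na(.data$partner_atc) ~ "warfarin_combo",
        TRUE ~ NA_character_
      ),
      partner_atc = if_else(.data$triggered_rule %in% "warfarin_combo",
                            .data$partner_atc, NA_character_)
    ) |>
    filter(!is.na(.data$triggered_rule)) |>
    select("patient_id", "setting", anticoag_atc = "atc_code", "molecule",
           "triggered_rule", "partner_atc", "age", "renal_impairment")
  if (nrow(findings) == 0) empty else
    arrange(findings, .data$patient_id, .data$setting, .data$anticoag_atc)
}
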