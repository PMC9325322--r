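# Composite phenotype for hospitalization with a bleeding adverse drug
# event: ICD-10 diagnoses, INR, hemoglobin, antidote administration.

#' Bleeding diagnosis criterion
#'
#' Fires when any diagnosis of the index stay matches the KB's bleeding
#' code set (prefix matching on 3-4 character roots allowed).
#'
#' @param diagnoses long diagnosis tibble for one or more stays (see
#'   [stay_diagnoses()]), columns `patient_id`, `code`
#' @param bleeding_code_set character vector of ICD-10 codes/prefixes
#' @return tibble: `patient_id`, `fired` (logical), `evidence` (matching
#'   codes, comma-joined; `NA` when not fired)
#' @export
detect_by_diagnosis <- function(diagnoses, bleeding_code_set) {
  diagnoses |>
    mutate(hit = icd10_in_set(.data$code, bleeding_code_set)) |>
    group_by(.data$patient_id) |>
    summarise(
      fired = any(.data$hit),
      evidence = if (any(.data$hit)) {
        paste(sort(unique(.data$code[.data$hit])), collapse = ",")
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}

#' Over-anticoagulation (INR) criterion
#'
#' Fires when any INR measurement strictly exceeds `threshold` (default
#' 5; an INR of exactly 5 does not fire).
#'
#' @param labs lab tibble already restricted to the stay window, columns
#'   `patient_id`, `analyte`, `value`, `date`
#' @param threshold INR cut-off, strict inequality (default 5)
#' @return tibble: `patient_id`, `fired`, `evidence` (worst INR and date)
#' @export
detect_by_inr <- function(labs, threshold = 5) {
  labs |>
    filter(.data$analyte == "INR") |>
    group_by(.data$patient_id) |>
    summarise(
      fired = any(.data$value > threshold),
      evidence = if (any(.data$value > threshold)) {
        sprintf("INR %.1f on %s", max(.data$value),
                format(.data$date[which.max(.data$value)]))
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}

#' Anemia (hemoglobin) criterion
#'
#' Threshold mode (default): fires when any in-stay hemoglobin is at or
#' below the sex-specific lower usual value, 11 g/dL for men and 10 g/dL
#' for women (inclusive). Delta mode additionally requires a drop of at
#' least `delta` g/dL from the patient's pre-stay maximum, for cohorts
#' with baseline measurements.
#'
#' @param labs in-stay lab tibble (`patient_id`, `analyte`, `value`,
#'   `date`)
#' @param sex tibble `patient_id`, `sex` (`"M"`/`"F"`)
#' @param mode `"threshold"` (default) or `"delta"`
#' @param baseline_labs pre-stay lab tibble, required in delta mode
#' @param delta minimal drop from the pre-stay maximum, delta mode only
#'   (default 2 g/dL)
#' @return tibble: `patient_id`, `fired`, `evidence`
#' @export
detect_by_hemoglobin <- function(labs, sex, mode = c("threshold", "delta"),
                                 baseline_labs = NULL, delta = 2) {
  mode <- arg_match(mode)
  hb <- labs |> filter(.data$analyte == "hemoglobin")
  joined <- hb |> left_join(sex, by = "patient_id")
  if (any(is.na(joined$sex) | !(joined$sex %in% c("M", "F")))) {
    abort("detect_by_hemoglobin: unknown sex for some patients with hemoglobin values")
  }
  out <- joined |>
    mutate(threshold = if_else(.data$sex == "M", 11, 10),
           below = .data$value <= .data$threshold) |>
    group_by(.data$patient_id) |>
    summarise(
      fired = any(.data$below),
      evidence = if (any(.data$below)) {
        sprintf("Hb %.1f g/dL on %s", min(.data$value),
                format(.data$date[which.min(.data$value)]))
      } else {
        NA_character_
      },
      min_hb = suppressWarnings(min(.data$value)),
      .groups = "drop"
    )
  if (mode == "delta") {
    if (is.null(baseline_labs)) {
      abort("delta mode needs baseline_labs (pre-stay hemoglobin values)")
    }
    base <- baseline_labs |>
      filter(.data$analyte == "hemoglobin") |>
      group_by(.data$patient_id) |>
      summarise(base_hb = max(.data$value), .groups = "drop")
    out <- out |>
      left_join(base, by = "patient_id") |>
      mutate(fired = .data$fired & !is.na(.data$base_hb) &
               (.data$base_hb - .data$min_hb) >= delta,
             evidence = if_else(.data$fired, .data$evidence, NA_character_)) |>
      select(-"base_hb")
  }
  out |> select(-"min_hb")
}

#' Antidote administration criterion
#'
#' Fires when any in-stay administration belongs to the anticoagulant
#' antidote set (vitamin K B02BA02, idarucizumab V03AB37, andexanet alfa
#' V03AB38, prothrombin complex B02BD01).
#'
#' @param administrations in-stay administrations tibble
#' @param antidote_set character vector of antidote ATC codes
#' @return tibble: `patient_id`, `fired`, `evidence` (all antidotes seen)
#' @export
detect_by_antidote <- function(administrations, antidote_set) {
  administrations |>
    mutate(hit = normalize_atc(.data$atc_code) %in% normalize_atc(antidote_set)) |>
    group_by(.data$patient_id) |>
    summarise(
      fired = any(.data$hit),
      evidence = if (any(.data$hit)) {
        paste(sort(unique(.data$atc_code[.data$hit])), collapse = ",")
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}

#' Composite bleeding adverse-drug-event phenotype
#'
#' Disjunction of the four criteria over each patient's index stay; all
#' fired criteria are recorded, not just the first. The intended
#' denominator is patients with primary-care anticoagulant exposure in
#' the 30 days before the stay; pass that subset of patients.
#'
#' @inheritParams detect_anticoag_exposure
#' @param labs validated labs tibble
#' @param administrations validated administrations tibble
#' @param hb_mode hemoglobin criterion mode, `"threshold"` or `"delta"`
#' @param lab_margin_days widen the in-stay lab window by this many days
#'   on each side (default 0)
#' @return tibble, one row per patient: `patient_id`, `is_ade`,
#'   `criteria_fired` (comma-joined subset of
#'   `diagnosis,inr,hemoglobin,antidote`, `""` when none), plus one
#'   evidence column per criterion
#' @export
detect_bleeding_ade <- function(patients, stays, labs, administrations,
                                kb = load_kb(),
                                hb_mode = c("threshold", "delta"),
                                lab_margin_days = 0) {
  hb_mode <- arg_match(hb_mode)
  windows <- setting_windows(patients, stays)
  stay_win <- windows |>
    filter(!is.na(.data$hosp_end)) |>
    select("patient_id", "hosp_start", "hosp_end")

  index_dx <- stay_diagnoses(stays) |>
    semi_join(patients |>
                select("patient_id", admission_date = "index_admission_date"),
              by = c("patient_id", "admission_date"))
  d_diag <- detect_by_diagnosis(index_dx, kb$code_sets$bleeding_icd10)

  in_stay_labs <- labs |>
    inner_join(stay_win, by = "patient_id") |>
    filter(.data$date >= .data$hosp_start - lab_margin_days,
           .data$date <= .data$hosp_end + lab_margin_days)
  pre_stay_labs <- labs |>
    inner_join(stay_win, by = "patient_id") |>
    filter(.data$date < .data$hosp_start - lab_margin_days)
  d_inr <- detect_by_inr(in_stay_labs)
  d_hb <- detect_by_hemoglobin(
    in_stay_labs, patients |> select("patient_id", "sex"),
    mode = hb_mode, baseline_labs = pre_stay_labs
  )

  in_stay_admin <- administrations |>
    inner_join(stay_win, by = "patient_id") |>
    filter(.data$admin_date >= .data$hosp_start,
           .data$admin_date <= .data$hosp_end)
  d_anti <- detect_by_antidote(in_stay_admin, kb$code_sets$antidote_atc)

  merge_crit <- function(base, crit, name) {
    crit <- crit |>
      rename(!!paste0("fired_", name) := "fired",
             !!paste0("evidence_", name) := "evidence")
    left_join(base, crit, by = "patient_id")
  }
  out <- patients |> select("patient_id")
  out <- merge_crit(out, d_diag, "diagnosis")
  out <- merge_crit(out, d_inr, "inr")
  out <- merge_crit(out, d_hb, "hemoglobin")
  out <- merge_crit(out, d_anti, "antidote")
  out |>
    mutate(across(dplyr::starts_with("fired_"), ~ dplyr::coalesce(.x, FALSE))) |>
    mutate(
      is_ade = .data$fired_diagnosis | .data$fired_inr |
        .data$fired_hemoglobin | .data$fired_antidote,
      criteria_fired = purrr::pmap_chr(
        list(.data$fired_diagnosis, .data$fired_inr, .data$fired_hemoglobin,
             .data$fired_antidote),
        function(d, i, h, a) {
          paste(c("diagnosis", "inr", "hemoglobin", "antidote")[c(d, i, h, a)],
                collapse = ",")
        }
      )
    ) |>
    select("patient_id", "is_ade", "criteria_fired",
           dplyr::starts_with("evidence_"))
}
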