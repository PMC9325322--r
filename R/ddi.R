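# Drug-drug interaction screening against the knowledge base, PIM-DDI
# flagging, and mechanism tabulation.

#' Detect bleeding-risk drug-drug interactions
#'
#' Screens each patient's drug eras against the KB's bleeding-risk
#' interaction rules within one setting window (30 days pre-admission, or
#' the index stay). Co-exposure requires at least one day of era overlap
#' after clipping both eras to the window. One event is emitted per
#' (patient, unordered drug pair, setting); when several rules match the
#' same pair the most severe harmonized rule wins.
#'
#' @param patients,stays,eras,kb,window_days see
#'   [detect_anticoag_exposure()]
#' @param setting `"primary_care"`, `"hospital"`, or both (default)
#' @param include_heparin_switch keep rules tagged as modelling the
#'   temporary DOAC/heparin co-prescription around a switch (default
#'   `TRUE`)
#' @return tibble of DDI events: `patient_id`, `setting`, `drug_a_atc`
#'   (the anticoagulant side as oriented in the KB), `drug_b_atc`,
#'   `severity` (harmonized), `raw_theriaque_level`, `mechanism`,
#'   `is_pim_ddi` (initialized `FALSE`; see [flag_pim_ddi()]),
#'   `overlap_start`, `overlap_end`, `combo_id` (shared by events of one
#'   patient/setting/anticoagulant, so triple combinations can be
#'   reported)
#' @export
detect_ddi <- function(patients, stays, eras, kb = load_kb(),
                       setting = c("primary_care", "hospital"),
                       window_days = 30, include_heparin_switch = TRUE) {
  setting <- match.arg(setting, several.ok = TRUE)
  windows <- setting_windows(patients, stays, window_days)
  rules <- kb$interactions |> filter(.data$bleeding_risk)
  if (!include_heparin_switch) rules <- rules |> filter(!.data$heparin_switch)
  empty <- tibble(patient_id = character(), setting = character(),
                  drug_a_atc = character(), drug_b_atc = character(),
                  severity = character(), raw_theriaque_level = integer(),
                  mechanism = character(), is_pim_ddi = logical(),
                  overlap_start = as.Date(character()),
                  overlap_end = as.Date(character()), combo_id = character())

  events <- purrr::map_dfr(setting, function(s) {
    setting_eras <- eras_in_setting(eras, windows, s)
    if (nrow(setting_eras) == 0) return(NULL)
    codes <- unique(setting_eras$atc_code)
    purrr::pmap_dfr(
      rules |> select("drug_a_pattern", "drug_b_pattern", "severity",
                      "severity_theriaque", "mechanism"),
      function(drug_a_pattern, drug_b_pattern, severity, severity_theriaque,
               mechanism) {
        a_codes <- codes[match_atc(codes, drug_a_pattern)]
        b_codes <- codes[match_atc(codes, drug_b_pattern)]
        if (length(a_codes) == 0 || length(b_codes) == 0) return(NULL)
        a_eras <- setting_eras |> filter(.data$atc_code %in% a_codes)
        b_eras <- setting_eras |> filter(.data$atc_code %in% b_codes)
        hits <- a_eras |>
          inner_join(b_eras, by = "patient_id", suffix = c("_a", "_b"),
                     relationship = "many-to-many") |>
          filter(.data$atc_code_a != .data$atc_code_b,
                 .data$start_a <= .data$end_b, .data$start_b <= .data$end_a)
        if (nrow(hits) == 0) return(NULL)
        hits |>
          group_by(.data$patient_id, drug_a_atc = .data$atc_code_a,
                   drug_b_atc = .data$atc_code_b) |>
          summarise(
            overlap_start = min(pmax(.data$start_a, .data$start_b)),
            overlap_end = max(pmin(.data$end_a, .data$end_b)),
            .groups = "drop"
          ) |>
          mutate(setting = s, severity = severity,
                 raw_theriaque_level = severity_theriaque,
                 mechanism = mechanism)
      }
    )
  })
  if (is.null(events) || nrow(events) == 0) return(empty)

  # one event per unordered pair; most severe harmonized class wins
  events |>
    mutate(
      pair_key = canonical_pair_key(.data$drug_a_atc, .data$drug_b_atc),
      sev_rank = match(.data$severity, SEVERITY_LEVELS)
    ) |>
    group_by(.data$patient_id, .data$setting, .data$pair_key) |>
    arrange(dplyr::desc(.data$sev_rank), .data$raw_theriaque_level) |>
    slice(1) |>
    ungroup() |>
    mutate(is_pim_ddi = FALSE,
           combo_id = paste(.data$patient_id, .data$setting,
                            .data$drug_a_atc, sep = "|")) |>
    select("patient_id", "setting", "drug_a_atc", "drug_b_atc", "severity",
           "raw_theriaque_level", "mechanism", "is_pim_ddi",
           "overlap_start", "overlap_end", "combo_id") |>
    arrange(.data$patient_id, .data$setting, .data$drug_a_atc, .data$drug_b_atc)
}

#' Flag DDI events whose anticoagulant member is a PIM
#'
#' An event is a PIM-DDI when its anticoagulant member has a PIM finding
#' in the same patient and setting, or when the pair itself triggers a
#' warfarin Beers combination rule (the pair is simultaneously the DDI and
#' the reason the anticoagulant is inappropriate).
#'
#' @param ddi_events output of [detect_ddi()]
#' @param pim_findings output of [classify_pim()] for the same cohort
#' @param kb knowledge base (anticoagulant set and combo patterns)
#' @return `ddi_events` with `is_pim_ddi` set
#' @export
flag_pim_ddi <- function(ddi_events, pim_findings, kb = load_kb()) {
  if (nrow(ddi_events) == 0) return(ddi_events)
  anticoag <- kb$code_sets$anticoagulant_atc
  pim_keys <- pim_findings |>
    distinct(.data$patient_id, .data$setting, .data$anticoag_atc) |>
    mutate(has_pim = TRUE)
  combo_rules <- kb$pim_rules |> filter(lengths(.data$partner_patterns) > 0)
  pair_is_combo <- function(a, b) {
    out <- rep(FALSE, length(a))
    for (i in seq_len(nrow(combo_rules))) {
      patterns <- combo_rules$partner_patterns[[i]]
      ac <- combo_rules$anticoag_atc[i]
      out <- out |
        (a == ac & match_any_atc(b, patterns)) |
        (b == ac & match_any_atc(a, patterns))
    }
    out
  }
  ddi_events |>
    mutate(
      anticoag_member = case_when(
        .data$drug_a_atc %in% anticoag ~ .data$drug_a_atc,
        .data$drug_b_atc %in% anticoag ~ .data$drug_b_atc,
        TRUE ~ NA_character_
      )
    ) |>
    left_join(pim_keys,
              by = c("patient_id", "setting",
                     anticoag_member = "anticoag_atc")) |>
    mutate(
      is_pim_ddi = dplyr::coalesce(.data$has_pim, FALSE) |
        pair_is_combo(.data$drug_a_atc, .data$drug_b_atc)
    ) |>
    select(-"has_pim", -"anticoag_member")
}

#' Tabulate interaction mechanisms per setting
#'
#' Patient-level mechanism counts: a patient contributes to every
#' mechanism class in which they have at least one event. Top-level
#' percentages (pharmacodynamic vs pharmacokinetic) are over the sum of
#' the two class counts; pharmacokinetic subtype percentages are over the
#' pharmacokinetic patient total.
#'
#' @param ddi_events output of [detect_ddi()] (optionally filtered, e.g.
#'   to PIM-DDI events)
#' @return tibble: `setting`, `mechanism` (`"PD"`, `"PK"`, or a PK
#'   subtype), `level` (`"class"` or `"pk_subtype"`), `n_patients`, `pct`
#' @export
tabulate_mechanisms <- function(ddi_events) {
  if (nrow(ddi_events) == 0) {
    return(tibble(setting = character(), mechanism = character(),
                  level = character(), n_patients = integer(),
                  pct = numeric()))
  }
  by_class <- ddi_events |>
    mutate(class = if_else(.data$mechanism == "PD", "PD", "PK")) |>
    distinct(.data$setting, .data$class, .data$patient_id) |>
    count(.data$setting, .data$class, name = "n_patients") |>
    group_by(.data$setting) |>
    mutate(pct = pct_of(.data$n_patients, sum(.data$n_patients))) |>
    ungroup() |>
    rename(mechanism = "class") |>
    mutate(level = "class")
  pk_totals <- by_class |>
    filter(.data$mechanism == "PK") |>
    select("setting", pk_total = "n_patients")
  by_subtype <- ddi_events |>
    filter(.data$mechanism != "PD") |>
    distinct(.data$setting, .data$mechanism, .data$patient_id) |>
    count(.data$setting, .data$mechanism, name = "n_patients") |>
    inner_join(pk_totals, by = "setting") |>
    mutate(pct = pct_of(.data$n_patients, .data$pk_total), level = "pk_subtype") |>
    select(-"pk_total")
  bind_rows(by_class, by_subtype) |>
    select("setting", "mechanism", "level", "n_patients", "pct") |>
    arrange(.data$setting, dplyr::desc(.data$level == "class"), .data$mechanism)
}

#' Table-style drug combination labels for DDI events
#'
#' Builds reporting labels per event: `molecule-partner` pairs, expanded
#' to `molecule-beers_partner-partner` triples when the event belongs to a
#' warfarin Beers combination context (the anticoagulant is PIM through a
#' partner drug different from the event's own partner).
#'
#' @inheritParams flag_pim_ddi
#' @return `ddi_events` with additional `combination` (label) and
#'   `association_type` (`"PIM-DDI"` or `"DDI"`) columns
#' @export
label_combinations <- function(ddi_events, pim_findings, kb = load_kb()) {
  anticoag <- kb$code_sets$anticoagulant_atc
  combo_pim <- pim_findings |>
    filter(.data$triggered_rule == "warfarin_combo") |>
    select("patient_id", "setting", "anticoag_atc",
           beers_partner = "partner_atc")
  ddi_events |>
    mutate(
      anticoag_atc = if_else(.data$drug_a_atc %in% anticoag,
                             .data$drug_a_atc, .data$drug_b_atc),
      partner_atc = if_else(.data$drug_a_atc %in% anticoag,
                            .data$drug_b_atc, .data$drug_a_atc)
    ) |>
    left_join(combo_pim, by = c("patient_id", "setting", "anticoag_atc")) |>
    mutate(
      combination = case_when(
        !is.na(.data$beers_partner) & .data$beers_partner != .data$partner_atc ~
          paste(anticoag_molecule(.data$anticoag_atc), .data$beers_partner,
                .data$partner_atc, sep = "-"),
        TRUE ~ paste(anticoag_molecule(.data$anticoag_atc),
                     .data$partner_atc, sep = "-")
      ),
      association_type = if_else(.data$is_pim_ddi, "PIM-DDI", "DDI")
    ) |>
    select(-"beers_partner")
}
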