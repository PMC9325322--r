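# Anticoagulant treatment pathway across the primary-care/hospital
# transition, and Sankey-style flow aggregation.

PATHWAY_LEVELS <- c("continued", "discontinued_bleeding",
                    "discontinued_surgery", "discontinued_other",
                    "initiated_in_hospital", "none")

#' Classify each patient's anticoagulant pathway
#'
#' Exactly one label per patient: `continued` when exposed in both
#' settings (molecule switches count as continued; anticoagulation-level
#' semantics); `discontinued_*` when exposed pre-hospital only, with
#' reason precedence bleeding > surgery > other (bleeding from the ADE
#' phenotype, surgery from the index stay type); `initiated_in_hospital`
#' when exposed in hospital only; `none` otherwise.
#'
#' @param exposures output of [detect_anticoag_exposure()]
#' @param ade output of [detect_bleeding_ade()]
#' @inheritParams detect_anticoag_exposure
#' @return tibble: `patient_id`, `pathway` (factor over the six labels),
#'   plus the `pre`/`hosp` exposure flags used
#' @export
classify_pathway <- function(patients, stays, exposures, ade) {
  exp_flags <- exposures |>
    distinct(.data$patient_id, .data$setting) |>
    mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "setting", values_from = "flag",
                       values_fill = FALSE)
  for (col in c("primary_care", "hospital")) {
    if (!col %in% names(exp_flags)) exp_flags[[col]] <- FALSE
  }
  stay_type <- setting_windows(patients, stays) |>
    select("patient_id", "stay_type")
  patients |>
    select("patient_id") |>
    left_join(exp_flags, by = "patient_id") |>
    left_join(ade |> select("patient_id", "is_ade"), by = "patient_id") |>
    left_join(stay_type, by = "patient_id") |>
    mutate(
      across(c("primary_care", "hospital"), ~ dplyr::coalesce(.x, FALSE)),
      is_ade = dplyr::coalesce(.data$is_ade, FALSE),
      pathway = case_when(
        .data$primary_care & .data$hospital ~ "continued",
        .data$primary_care & .data$is_ade ~ "discontinued_bleeding",
        .data$primary_care & .data$stay_type %in% "surgery" ~
          "discontinued_surgery",
        .data$primary_care ~ "discontinued_other",
        .data$hospital ~ "initiated_in_hospital",
        TRUE ~ "none"
      ),
      pathway = factor(.data$pathway, levels = PATHWAY_LEVELS)
    ) |>
    select("patient_id", "pathway", pre_exposed = "primary_care",
           hosp_exposed = "hospital")
}

#' Aggregate pathway labels into flow counts
#'
#' Counts and percentages per category, plus the discontinued parent
#' total (its subcategories sum to it by construction). Percentages are
#' over patients exposed before admission for the continued/discontinued
#' flows and over all labelled patients for initiation.
#'
#' @param labels output of [classify_pathway()]
#' @return tibble of class `pimddi_flows`: `category`, `n`, `denominator`,
#'   `pct`; zero rows for an empty cohort
#' @export
aggregate_flows <- function(labels) {
  if (nrow(labels) == 0) {
    out <- tibble(category = character(), n = integer(),
                  denominator = integer(), pct = numeric())
    class(out) <- c("pimddi_flows", class(out))
    return(out)
  }
  counts <- labels |> count(.data$pathway, .drop = FALSE, name = "n")
  n_of <- function(cat) sum(counts$n[counts$pathway == cat])
  pre_total <- n_of("continued") + n_of("discontinued_bleeding") +
    n_of("discontinued_surgery") + n_of("discontinued_other")
  total <- sum(counts$n[counts$pathway != "none"])
  disc_total <- pre_total - n_of("continued")
  out <- bind_rows(
    tibble(category = "continued", n = n_of("continued"),
           denominator = pre_total),
    tibble(category = "discontinued", n = disc_total, denominator = pre_total),
    tibble(category = "discontinued_bleeding",
           n = n_of("discontinued_bleeding"), denominator = disc_total),
    tibble(category = "discontinued_surgery",
           n = n_of("discontinued_surgery"), denominator = disc_total),
    tibble(category = "discontinued_other", n = n_of("discontinued_other"),
           denominator = disc_total),
    tibble(category = "initiated_in_hospital",
           n = n_of("initiated_in_hospital"), denominator = total)
  ) |>
    mutate(pct = pct_of(.data$n, .data$denominator))
  class(out) <- c("pimddi_flows", class(out))
  out
}

#' Source/target flow table for Sankey renderers
#'
#' @param labels output of [classify_pathway()]
#' @return tibble: `source`, `target`, `count`, consumable by generic
#'   Sankey tools
#' @export
pathway_flow_edges <- function(labels) {
  labels |>
    filter(.data$pathway != "none") |>
    mutate(
      source = if_else(.data$pre_exposed, "anticoagulant_before_admission",
                       "no_anticoagulant_before_admission"),
      target = as.character(.data$pathway)
    ) |>
    count(.data$source, .data$target, name = "count")
}
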