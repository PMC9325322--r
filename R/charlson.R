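# Charlson comorbidity index from look-back ICD-10 diagnoses (Quan
# ICD-10 coding algorithm, original Charlson weights; shipped as a
# plain-text mapping fixture so users can substitute their own).

#' Load the shipped Charlson ICD-10 mapping
#'
#' @param path optional path to a custom mapping CSV with columns
#'   `condition`, `weight`, `prefixes` (semicolon-joined, dotless ICD-10
#'   prefixes)
#' @return tibble: `condition`, `weight`, `prefixes` (list column)
#' @export
charlson_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "charlson_quan_icd10.csv", package = "pimddi")
  }
  readr::read_csv(path, col_types = "cic", progress = FALSE) |>
    mutate(prefixes = strsplit(.data$prefixes, ";", fixed = TRUE))
}

#' Charlson comorbidity index per patient
#'
#' Sums condition weights over the distinct comorbidity categories mapped
#' from each patient's look-back diagnoses (prefix matching; duplicate
#' codes within a category count once). The two hierarchical pairs are
#' resolved the standard way: complicated diabetes supersedes
#' uncomplicated, metastatic disease supersedes localized malignancy, and
#' moderate/severe liver disease supersedes mild.
#'
#' @param diagnoses tibble with columns `patient_id`, `code` (1-year
#'   look-back diagnoses; see [stay_diagnoses()])
#' @param mapping mapping tibble from [charlson_mapping()]
#' @return tibble: `patient_id`, `charlson` (non-negative integer); all
#'   input patients appear, score 0 when no code maps
#' @export
charlson_index <- function(diagnoses, mapping = charlson_mapping()) {
  ids <- distinct(diagnoses, .data$patient_id)
  if (nrow(diagnoses) == 0) {
    return(ids |> mutate(charlson = integer()))
  }
  hits <- purrr::pmap_dfr(
    mapping,
    function(condition, weight, prefixes) {
      hit <- diagnoses |>
        filter(icd10_in_set(.data$code, prefixes)) |>
        distinct(.data$patient_id)
      if (nrow(hit) == 0) return(NULL)
      hit |> mutate(condition = condition, weight = weight)
    }
  )
  if (nrow(hits) == 0) {
    return(ids |> mutate(charlson = 0L))
  }
  supersede <- function(df, winner, loser) {
    losers <- df |>
      filter(.data$condition == winner) |>
      distinct(.data$patient_id) |>
      mutate(condition = loser)
    anti_join(df, losers, by = c("patient_id", "condition"))
  }
  hits <- hits |>
    supersede("diabetes_with_complication", "diabetes_without_complication") |>
    supersede("metastatic_solid_tumor", "any_malignancy") |>
    supersede("moderate_severe_liver_disease", "mild_liver_disease")
  scores <- hits |>
    group_by(.data$patient_id) |>
    summarise(charlson = as.integer(sum(.data$weight)), .groups = "drop")
  ids |>
    left_join(scores, by = "patient_id") |>
    mutate(charlson = dplyr::coalesce(.data$charlson, 0L))
}
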