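# Descriptive tables and the multivariable logistic bleeding-risk model.

#' Patient-level prevalence table for one setting
#'
#' For the chosen setting: patients exposed per anticoagulant molecule,
#' patients with at least one PIM / DDI / PIM-DDI (total and per
#' molecule), mean +/- SD distinct interaction pairs per patient (over
#' all exposed patients, zeros included), and patient counts at Theriaque
#' severity levels 1 and 2. Percentages are of the setting denominator
#' (patients exposed in that setting), rounded half-up to one decimal as
#' in printed tables; `n` and `denominator` stay exact for recomputation.
#'
#' @param exposures output of [detect_anticoag_exposure()]
#' @param pim_findings output of [classify_pim()]
#' @param ddi_events output of [flag_pim_ddi()]
#' @param setting `"primary_care"` or `"hospital"`
#' @return tibble of class `pimddi_prevalence`: `setting`, `measure`,
#'   `drug`, `n`, `denominator`, `pct`, `mean_events`, `sd_events`
#' @export
prevalence_table <- function(exposures, pim_findings, ddi_events,
                             setting = c("primary_care", "hospital")) {
  setting <- arg_match(setting)
  s <- setting
  exp_s <- exposures |> filter(.data$setting == s)
  denom <- n_distinct(exp_s$patient_id)
  empty <- tibble(setting = character(), measure = character(),
                  drug = character(), n = integer(), denominator = integer(),
                  pct = numeric(), mean_events = numeric(), sd_events = numeric())
  if (denom == 0) {
    class(empty) <- c("pimddi_prevalence", class(empty))
    return(empty)
  }
  pim_s <- pim_findings |> filter(.data$setting == s)
  ddi_s <- ddi_events |> filter(.data$setting == s)
  pimddi_s <- ddi_s |> filter(.data$is_pim_ddi)

  count_rows <- function(measure, df, drug_col) {
    total <- tibble(measure = measure, drug = "all",
                    n = n_distinct(df$patient_id))
    by_drug <- df |>
      mutate(drug = anticoag_molecule(.data[[drug_col]])) |>
      filter(!is.na(.data$drug)) |>
      group_by(.data$drug) |>
      summarise(n = n_distinct(.data$patient_id), .groups = "drop") |>
      mutate(measure = measure)
    bind_rows(total, by_drug)
  }
  events_stats <- function(df) {
    per_patient <- df |>
      count(.data$patient_id, name = "k") |>
      right_join(exp_s |> distinct(.data$patient_id), by = "patient_id") |>
      mutate(k = dplyr::coalesce(.data$k, 0L))
    c(mean = mean(per_patient$k), sd = sd(per_patient$k))
  }
  severity_rows <- function(measure, df) {
    purrr::map_dfr(c(1L, 2L), function(lev) {
      tibble(measure = paste0(measure, "_level", lev), drug = "all",
             n = n_distinct(df$patient_id[df$raw_theriaque_level %in% lev]))
    })
  }

  ddi_stats <- events_stats(ddi_s)
  pimddi_stats <- events_stats(pimddi_s)
  out <- bind_rows(
    count_rows("anticoagulant", exp_s, "atc_code"),
    count_rows("pim", pim_s, "anticoag_atc"),
    count_rows("ddi", ddi_s, "drug_a_atc"),
    severity_rows("ddi", ddi_s),
    count_rows("pim_ddi", pimddi_s, "drug_a_atc"),
    severity_rows("pim_ddi", pimddi_s)
  ) |>
    mutate(
      setting = s,
      denominator = denom,
      pct = pct_of(.data$n, denom),
      mean_events = case_when(
        .data$measure == "ddi" & .data$drug == "all" ~ ddi_stats[["mean"]],
        .data$measure == "pim_ddi" & .data$drug == "all" ~ pimddi_stats[["mean"]],
        TRUE ~ NA_real_
      ),
      sd_events = case_when(
        .data$measure == "ddi" & .data$drug == "all" ~ ddi_stats[["sd"]],
        .data$measure == "pim_ddi" & .data$drug == "all" ~ pimddi_stats[["sd"]],
        TRUE ~ NA_real_
      )
    ) |>
    select("setting", "measure", "drug", "n", "denominator", "pct",
           "mean_events", "sd_events")
  class(out) <- c("pimddi_prevalence", class(out))
  out
}

#' Bleeding-ADE rates by exposure group and drug combination
#'
#' Rate = patients with a bleeding ADE / patients in the group, for the
#' PIM, DDI and PIM-DDI groups and for each drug combination label (pairs,
#' plus warfarin Beers triples). Empty groups yield a missing rate.
#'
#' @param ade output of [detect_bleeding_ade()]
#' @param pim_findings,ddi_events screened findings (primary-care setting
#'   rows are used, matching the phenotype's denominator)
#' @param kb knowledge base
#' @param min_group_size drop combination rows smaller than this (default
#'   1 = keep all)
#' @return tibble: `group`, `combination` (`NA` for the three measure
#'   groups), `n_group`, `n_ade`, `rate_pct`
#' @export
bleeding_rates_by_group <- function(ade, pim_findings, ddi_events,
                                    kb = load_kb(), min_group_size = 1) {
  ade_ids <- ade$patient_id[ade$is_ade]
  pim_pc <- pim_findings |> filter(.data$setting == "primary_care")
  ddi_pc <- ddi_events |> filter(.data$setting == "primary_care")
  group_row <- function(group, ids) {
    ids <- unique(ids)
    n <- length(ids)
    tibble(group = group, combination = NA_character_, n_group = n,
           n_ade = sum(ids %in% ade_ids),
           rate_pct = if (n > 0) pct_of(sum(ids %in% ade_ids), n) else NA_real_)
  }
  measures <- bind_rows(
    group_row("pim", pim_pc$patient_id),
    group_row("ddi", ddi_pc$patient_id),
    group_row("pim_ddi", ddi_pc$patient_id[ddi_pc$is_pim_ddi])
  )
  combos <- label_combinations(ddi_pc, pim_pc, kb) |>
    distinct(.data$patient_id, .data$combination, .data$association_type) |>
    group_by(.data$combination, .data$association_type) |>
    summarise(
      n_group = n_distinct(.data$patient_id),
      n_ade = n_distinct(.data$patient_id[.data$patient_id %in% ade_ids]),
      .groups = "drop"
    ) |>
    filter(.data$n_group >= min_group_size) |>
    mutate(group = paste0("combination_", tolower(.data$association_type)),
           rate_pct = pct_of(.data$n_ade, .data$n_group)) |>
    select("group", "combination", "n_group", "n_ade", "rate_pct") |>
    arrange(dplyr::desc(.data$n_group))
  bind_rows(measures, combos)
}

#' Fit the multivariable logistic bleeding-risk model
#'
#' Maximum-likelihood logistic regression of hospitalization for a
#' bleeding ADE on the standard covariate set: age (years, untransformed),
#' sex, history of stroke, previous bleeding event, diabetes, renal
#' disease, liver disease, cancer, hypertension, and the PIM, DDI and
#' PIM-DDI indicators. Odds ratios are exponentiated coefficients with
#' Wald 95% confidence intervals; p-values are raw (no multiplicity
#' correction).
#'
#' @param cohort_rows tibble with an `ade` outcome column and the
#'   covariates above (see [screen_cohort()]'s `cohort` component)
#' @param covariates covariate names entering the model; default is the
#'   standard 12-term set above. Override only for reduced fits (e.g.
#'   closed-form single-covariate checks)
#' @return object of class `pimddi_logistic`; use [generics::tidy()] for
#'   the OR table and [generics::glance()] for fit summaries
#' @export
fit_bleeding_logistic <- function(cohort_rows,
                                  covariates = c("age", "sex", "stroke",
                                                 "prev_bleed", "diabetes",
                                                 "renal", "liver", "cancer",
                                                 "hypertension", "pim", "ddi",
                                                 "pim_ddi")) {
  covars <- covariates
  assert_columns(cohort_rows, c("ade", covars), "cohort rows")
  binary_cols <- intersect(
    c("ade", "stroke", "prev_bleed", "diabetes", "renal", "liver", "cancer",
      "hypertension", "pim", "ddi", "pim_ddi"),
    c("ade", covars)
  )
  df <- cohort_rows |>
    mutate(across(dplyr::all_of(binary_cols), ~ as.integer(as.logical(.x))))
  if ("sex" %in% covars) df$sex <- factor(df$sex, levels = c("F", "M"))
  if (length(unique(df$ade)) < 2) {
    abort("outcome has a single class; logistic fit impossible")
  }
  form <- stats::as.formula(paste("ade ~", paste(covars, collapse = " + ")))
  mm <- stats::model.matrix(form, df)
  dec <- qr(mm)
  if (dec$rank < ncol(mm)) {
    dropped <- colnames(mm)[dec$pivot[seq(dec$rank + 1, ncol(mm))]]
    abort(glue::glue("singular design matrix; collinear column(s): ",
                     "{paste(dropped, collapse = ', ')}"))
  }
  fit <- withCallingHandlers(
    glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)[-1]
  if (any(abs(cf) > 15)) {
    worst <- names(cf)[which.max(abs(cf))]
    abort(glue::glue("(quasi-)perfect separation detected on covariate '{worst}'"))
  }
  structure(list(fit = fit, covariates = covars,
                 n = nrow(df), n_events = sum(df$ade)),
            class = "pimddi_logistic")
}

#' @export
print.pimddi_logistic <- function(x, ...) {
  cat("<pimddi logistic bleeding-risk model>\n")
  cat("  n =", x$n, " events =", x$n_events, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Odds-ratio table of a fitted bleeding-risk model
#'
#' @param x a `pimddi_logistic` object
#' @param ... unused
#' @return tibble: `term`, `or`, `conf.low`, `conf.high`, `p.value` (Wald
#'   95% intervals on the odds-ratio scale; intercept omitted)
#' @export
tidy.pimddi_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  z <- qnorm(0.975)
  out <- tibble(
    term = rownames(sm),
    or = exp(est),
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
  out[out$term != "(Intercept)", ]
}

#' One-row fit summary of a bleeding-risk model
#'
#' @param x a `pimddi_logistic` object
#' @param ... unused
#' @return tibble: `n`, `n_events`, `null.deviance`, `deviance`, `AIC`
#' @export
glance.pimddi_logistic <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         null.deviance = x$fit$null.deviance, deviance = x$fit$deviance,
         AIC = stats::AIC(x$fit))
}
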