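# Synthetic linked-cohort generator with full ground truth.
#
# Flags first, records second: each patient's PIM / DDI / PIM-DDI / ADE /
# pathway status is drawn at the configured prevalences, then dispensing,
# administration, stay and laboratory records are written so that the
# deterministic detection pipeline reproduces exactly those flags. Ages
# and renal status are shaped to be consistent with the Beers rules of
# the drawn PIM flag, so the marginal age distribution is approximate
# while rule consistency is exact.

# partner pools (ATC -> sampling weight), per anticoagulant
BEERS_PARTNER_POOL <- c(C01BD01 = 0.6, J01EE01 = 0.1, J01MA02 = 0.1,
                        J01FA09 = 0.1, M01AE01 = 0.1)
WARF_NONBEERS_POOL <- c(N02BE01 = 0.45, C10AA05 = 0.15, H03AA01 = 0.10,
                        N02AX02 = 0.15, B01AC06 = 0.15)
RIVA_POOL <- c(C01BD01 = 0.4, C08DB01 = 0.1, C08DA01 = 0.1, N06AB10 = 0.1,
               B01AC06 = 0.15, N02AX02 = 0.15)
APIX_POOL <- c(C01BD01 = 0.4, C08DA01 = 0.15, C08DB01 = 0.15, L04AD01 = 0.1,
               C01BD07 = 0.1, B01AC06 = 0.1)
DAB_POOL <- c(C01BD01 = 0.5, C08DA01 = 0.25, B01AC06 = 0.25)
NOISE_POOL <- c("A10BA02", "C07AB07", "C03CA01", "C09AA05", "A02BC01",
                "B03BB01")
ANTICOAG_ATC <- c(warfarin = "B01AA03", rivaroxaban = "B01AF01",
                  apixaban = "B01AF02", dabigatran = "B01AE07")
COMORB_CODE <- c(stroke = "I639", diabetes = "E119", liver = "K746",
                 cancer = "C189", hypertension = "I10")
BLEED_DX_POOL <- c("R31", "K921", "D62", "K625", "R040", "K922", "Y442")
ANTIDOTE_POOL <- c(B02BA02 = 0.80, B02BD01 = 0.15, V03AB37 = 0.03,
                   V03AB38 = 0.02)

#' Configuration of the synthetic-cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: a cohort of
#' elderly patients (ages centred near 79) on oral anticoagulants
#' (warfarin 46.6%, rivaroxaban 23.9%, apixaban 18.3%, dabigatran 11.6%
#' of primary-care users), planted prevalences of 22.9% PIM, 47.2% DDI
#' and 19.5% PIM-DDI, a marginal bleeding-ADE rate of 17.1% produced by a
#' planted logistic model (odds ratios per covariate), an ADE criterion
#' mix of 37.5% diagnosis / 58.7% laboratory (split between INR and
#' hemoglobin) / 3.8% antidote, 48.6% treatment continuation in hospital,
#' and 0.4437 hospital-only initiators per primary-care patient.
#'
#' @param n_patients primary-care-exposed cohort size
#' @param seed integer seed (controls every draw)
#' @param start_date,end_date index admission dates drawn uniformly here
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model
#' @param p_male probability of male sex
#' @param anticoag_shares named shares per molecule (normalized to 1)
#' @param p_pim,p_ddi,p_pim_ddi planted patient-level prevalences
#'   (primary-care setting); must satisfy `p_pim_ddi <= min(p_pim, p_ddi)`
#'   and `p_pim_ddi / p_pim >=` the warfarin share (warfarin Beers-combo
#'   PIM implies a PIM-DDI by construction)
#' @param p_pim_via_age among dabigatran/rivaroxaban PIM patients, share
#'   realized through age >= 75 (the rest through age 65-74 with renal
#'   impairment)
#' @param p_renal_baseline renal-impairment probability where the Beers
#'   rules leave it free
#' @param comorbidity_prevalence named probabilities for stroke,
#'   prev_bleed, diabetes, liver, cancer, hypertension
#' @param outcome_or named planted odds ratios of the bleeding-outcome
#'   model (age is per year)
#' @param target_ade_rate marginal ADE rate; the intercept is calibrated
#'   by root finding to hit it within 0.5 percentage points
#' @param ade_criterion_mix named shares of the realized detection
#'   criterion among ADE patients (diagnosis, inr, hemoglobin, antidote)
#' @param p_continued probability that therapy continues in hospital
#' @param p_surgery probability of a surgical index stay
#' @param p_switch among continued patients, probability of a molecule
#'   switch at admission
#' @param initiated_ratio hospital-only initiators per primary-care
#'   patient
#' @param duration_mix shares of pre-admission exposure duration classes
#'   (<=1, 1-3, 3-6, >6 months)
#' @param mean_extra_partners Poisson mean of additional interacting
#'   co-medications for patients with a DDI (so distinct interaction
#'   pairs average near 3 among DDI patients)
#' @param supply_days assumed dispensing coverage
#' @return a validated config list of class `pimddi_config`
#' @export
cohort_config <- function(
    n_patients = 1000, seed = 1,
    start_date = as.Date("2015-01-01"), end_date = as.Date("2017-12-31"),
    age_mean = 79, age_sd = 8, age_min = 65, age_max = 100,
    p_male = 0.578,
    anticoag_shares = c(warfarin = 0.466, rivaroxaban = 0.239,
                        apixaban = 0.183, dabigatran = 0.116),
    p_pim = 0.229, p_ddi = 0.472, p_pim_ddi = 0.195,
    p_pim_via_age = 0.85, p_renal_baseline = 0.15,
    comorbidity_prevalence = c(stroke = 0.05, prev_bleed = 0.10,
                               diabetes = 0.25, liver = 0.03, cancer = 0.05,
                               hypertension = 0.55),
    outcome_or = c(age = 1.03, sex_m = 1.19, stroke = 1.17, prev_bleed = 4.23,
                   diabetes = 1.29, renal = 1.98, liver = 1.72, cancer = 2.68,
                   hypertension = 1.72, pim = 1.08, ddi = 1.15,
                   pim_ddi = 1.23),
    target_ade_rate = 0.171,
    ade_criterion_mix = c(diagnosis = 0.375, inr = 0.290, hemoglobin = 0.297,
                          antidote = 0.038),
    p_continued = 0.486, p_surgery = 0.364, p_switch = 0.03,
    initiated_ratio = 0.4437,
    duration_mix = c(le1m = 0.065, m1to3 = 0.093, m3to6 = 0.082,
                     gt6m = 0.759),
    mean_extra_partners = 2, supply_days = 30) {
  cfg <- as.list(environment())
  probs <- c(p_male, p_pim, p_ddi, p_pim_ddi, p_pim_via_age, p_renal_baseline,
             comorbidity_prevalence, target_ade_rate, p_continued, p_surgery,
             p_switch)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  for (nm in c("anticoag_shares", "ade_criterion_mix", "duration_mix")) {
    s <- sum(cfg[[nm]])
    if (abs(s - 1) > 0.05) {
      abort(glue::glue("{nm} must sum to 1 (got {round(s, 3)})"))
    }
    cfg[[nm]] <- cfg[[nm]] / s
  }
  if (p_pim_ddi > min(p_pim, p_ddi) + 1e-9) {
    abort("p_pim_ddi cannot exceed min(p_pim, p_ddi)")
  }
  w <- cfg$anticoag_shares[["warfarin"]]
  if (p_pim > 0 && p_pim_ddi / p_pim < w - 1e-9) {
    abort(paste("p_pim_ddi / p_pim below the warfarin share: warfarin",
                "Beers-combo PIM always carries a PIM-DDI, so this target",
                "mix is infeasible"))
  }
  if (n_patients < 1) abort("n_patients must be positive")
  structure(cfg, class = "pimddi_config")
}

#' @noRd
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' @noRd
sample_pool <- function(pool, n) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

#' Draw per-patient covariates and planted flags
#'
#' The covariate/flag engine behind [generate_cohort()]: draws molecule,
#' demographics (rule-consistent with the drawn PIM flag), comorbidities,
#' the PIM / DDI / PIM-DDI flags at their planted prevalences, the
#' calibrated logistic bleeding outcome, its realized detection
#' criterion, and the pathway label. Useful on its own for
#' parameter-recovery experiments that do not need raw records.
#'
#' @param config a [cohort_config()] object
#' @return tibble, one row per primary-care patient, with covariates,
#'   flags, the linear predictor `eta` and the calibrated intercept as
#'   the `"intercept"` attribute
#' @export
simulate_covariates <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pimddi_config"))
  set.seed(config$seed)
  simulate_covariates_impl(config)
}

#' @noRd
simulate_covariates_impl <- function(config) {
  n <- config$n_patients
  shares <- config$anticoag_shares
  molecule <- sample(names(shares), n, replace = TRUE, prob = shares)
  pim <- runif(n) < config$p_pim

  # warfarin PIM (a Beers combo) is always a PIM-DDI; DOAC PIM patients
  # get a compensated probability so the marginal hits p_pim_ddi
  w <- shares[["warfarin"]]
  r_doac <- if (config$p_pim > 0 && w < 1) {
    max(0, min(1, (config$p_pim_ddi / config$p_pim - w) / (1 - w)))
  } else {
    0
  }
  pim_ddi <- pim & ifelse(molecule == "warfarin", TRUE, runif(n) < r_doac)
  # among PIM patients every anticoagulant DDI is a PIM-DDI, so DDI status
  # is pinned there; non-PIM patients carry the remaining DDI mass
  p_ddi_nonpim <- if (config$p_pim < 1) {
    min(1, max(0, (config$p_ddi - config$p_pim_ddi) / (1 - config$p_pim)))
  } else {
    0
  }
  ddi <- ifelse(pim, pim_ddi, runif(n) < p_ddi_nonpim)

  # ages/renal shaped to agree with the drawn PIM flag (Beers rules)
  age <- floor(rtrunc_norm(n, config$age_mean, config$age_sd,
                           config$age_min, config$age_max))
  renal <- runif(n) < config$p_renal_baseline
  age_rule <- molecule %in% c("dabigatran", "rivaroxaban")
  via_age <- runif(n) < config$p_pim_via_age
  i <- pim & age_rule & via_age
  age[i] <- floor(rtrunc_norm(sum(i), config$age_mean, config$age_sd,
                              75, config$age_max))
  i <- pim & age_rule & !via_age
  age[i] <- floor(rtrunc_norm(sum(i), config$age_mean, config$age_sd,
                              config$age_min, 74.999))
  renal[i] <- TRUE
  i <- !pim & age_rule
  age[i] <- floor(rtrunc_norm(sum(i), config$age_mean, config$age_sd,
                              config$age_min, 74.999))
  renal[i] <- FALSE
  i <- molecule == "apixaban"
  renal[i] <- pim[i]

  sex <- ifelse(runif(n) < config$p_male, "M", "F")
  cp <- config$comorbidity_prevalence
  stroke <- runif(n) < cp[["stroke"]]
  prev_bleed <- runif(n) < cp[["prev_bleed"]]
  diabetes <- runif(n) < cp[["diabetes"]]
  liver <- runif(n) < cp[["liver"]]
  cancer <- runif(n) < cp[["cancer"]]
  hypertension <- runif(n) < cp[["hypertension"]]

  beta <- log(config$outcome_or)
  eta_x <- beta[["age"]] * age + beta[["sex_m"]] * (sex == "M") +
    beta[["stroke"]] * stroke + beta[["prev_bleed"]] * prev_bleed +
    beta[["diabetes"]] * diabetes + beta[["renal"]] * renal +
    beta[["liver"]] * liver + beta[["cancer"]] * cancer +
    beta[["hypertension"]] * hypertension + beta[["pim"]] * pim +
    beta[["ddi"]] * ddi + beta[["pim_ddi"]] * pim_ddi

  target <- config$target_ade_rate
  f <- function(b0) mean(plogis(b0 + eta_x)) - target
  if (f(-40) > 0 || f(20) < 0) {
    abort("target ADE rate unreachable with the planted coefficients")
  }
  b0 <- uniroot(f, c(-40, 20), tol = 1e-8)$root
  eta <- b0 + eta_x
  ade <- runif(n) < plogis(eta)
  criterion <- rep(NA_character_, n)
  criterion[ade] <- sample(names(config$ade_criterion_mix), sum(ade),
                           replace = TRUE, prob = config$ade_criterion_mix)

  index_date <- config$start_date +
    floor(runif(n) * (as.numeric(config$end_date - config$start_date) + 1))
  stay_type <- ifelse(runif(n) < config$p_surgery, "surgery", "medicine")
  continued <- runif(n) < config$p_continued
  pathway <- dplyr::case_when(
    continued ~ "continued",
    ade ~ "discontinued_bleeding",
    stay_type == "surgery" ~ "discontinued_surgery",
    TRUE ~ "discontinued_other"
  )
  duration_class <- sample(seq_along(config$duration_mix), n, replace = TRUE,
                           prob = config$duration_mix)

  pim_rule <- dplyr::case_when(
    pim & molecule == "warfarin" ~ "warfarin_combo",
    pim & age_rule & age >= 75 ~ "age_ge_75",
    pim ~ "age_ge_65_renal",
    TRUE ~ NA_character_
  )

  out <- tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    molecule = molecule, age = as.integer(age), sex = sex, renal = renal,
    stroke = stroke, prev_bleed = prev_bleed, diabetes = diabetes,
    liver = liver, cancer = cancer, hypertension = hypertension,
    pim = pim, pim_rule = pim_rule, ddi = ddi, pim_ddi = pim_ddi,
    ade = ade, ade_criterion = criterion, pathway = pathway,
    continued = continued, stay_type = stay_type,
    duration_class = as.integer(duration_class),
    index_date = index_date, eta = eta
  )
  attr(out, "intercept") <- b0
  out
}

#' @noRd
draw_partners <- function(molecule, pim, ddi, mean_extra) {
  if (!ddi) return(character(0))
  main_pool <- switch(molecule,
    warfarin = if (pim) BEERS_PARTNER_POOL else WARF_NONBEERS_POOL,
    rivaroxaban = RIVA_POOL, apixaban = APIX_POOL, dabigatran = DAB_POOL
  )
  extra_pool <- switch(molecule,
    warfarin = if (pim) c(BEERS_PARTNER_POOL, WARF_NONBEERS_POOL) else
      WARF_NONBEERS_POOL,
    rivaroxaban = RIVA_POOL, apixaban = APIX_POOL, dabigatran = DAB_POOL
  )
  first <- sample_pool(main_pool, 1)
  n_extra <- min(rpois(1, mean_extra), length(extra_pool) - 1)
  extras <- character(0)
  if (n_extra > 0) {
    candidates <- setdiff(names(extra_pool), first)
    extras <- sample(candidates, n_extra, prob = extra_pool[candidates])
  }
  unique(c(first, extras))
}

#' @noRd
month_before <- function(date, years_back) {
  y <- as.integer(format(date, "%Y")) - years_back
  m <- as.integer(format(date, "%m")) - 1L
  y <- ifelse(m == 0L, y - 1L, y)
  m <- ifelse(m == 0L, 12L, m)
  as.Date(sprintf("%04d-%02d-01", y, m))
}

#' Generate a synthetic linked cohort
#'
#' Draws per-patient ground truth (see [simulate_covariates()]) and emits
#' the five raw tables such that [screen_cohort()] reproduces the planted
#' flags exactly: anticoagulant and partner dispensings in the look-back
#' year, index and prior hospital stays with ICD-10 codes realizing the
#' planted comorbidities and ADE criteria, in-hospital administrations
#' for continued therapy, partner co-administrations, heparin
#' co-prescription and antidotes, and INR/hemoglobin results. A block of
#' hospital-only initiators (no pre-admission dispensing) is appended.
#'
#' @param config a [cohort_config()] object
#' @return list of class `pimddi_cohort`: `tables` (patients, dispensing,
#'   administrations, stays, labs), `truth` (per-patient ground truth;
#'   hospital-only initiators carry `NA` flags where a concept does not
#'   apply), `config`, and the calibrated `intercept`
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pimddi_config"))
  set.seed(config$seed)
  truth <- simulate_covariates_impl(config)
  intercept <- attr(truth, "intercept")
  n <- nrow(truth)

  truth$partners <- purrr::pmap(
    list(truth$molecule, truth$pim, truth$ddi),
    function(m, p, d) draw_partners(m, p, d, config$mean_extra_partners)
  )
  # warfarin-combo PIM needs a Beers partner even without further DDIs;
  # by construction warfarin PIM patients all have ddi = TRUE, and their
  # first partner comes from the Beers pool
  truth$n_ddi_pairs <- lengths(truth$partners)
  truth$beers_partner <- purrr::pmap_chr(
    list(truth$molecule, truth$pim, truth$partners),
    function(m, p, prt) {
      if (m == "warfarin" && p) min(prt[match_any_atc(
        prt, c("C01BD01", "J01EE01", "J01MA02", "J01FA*!J01FA10", "M01A*")
      )]) else NA_character_
    }
  )

  los <- ifelse(truth$stay_type == "surgery",
                sample(2:10, n, replace = TRUE),
                sample(2:14, n, replace = TRUE))
  discharge <- truth$index_date + los
  hosp_molecule <- ifelse(
    truth$continued & runif(n) < config$p_switch,
    sample(c("apixaban", "rivaroxaban"), n, replace = TRUE),
    truth$molecule
  )

  # ---- patients -------------------------------------------------------
  patients <- tibble(
    patient_id = truth$patient_id,
    sex = truth$sex,
    birth_year_month = month_before(truth$index_date, truth$age),
    index_admission_date = truth$index_date
  )

  # ---- dispensing -----------------------------------------------------
  n_disp <- c(1, 0, 0, 0)[truth$duration_class] +
    ifelse(truth$duration_class == 2, sample(2:3, n, replace = TRUE), 0) +
    ifelse(truth$duration_class == 3, sample(4:6, n, replace = TRUE), 0) +
    ifelse(truth$duration_class == 4, sample(7:12, n, replace = TRUE), 0)
  disp_anticoag <- tibble(
    patient_id = rep(truth$patient_id, n_disp),
    atc_code = rep(ANTICOAG_ATC[truth$molecule], n_disp),
    offset = unlist(lapply(n_disp, function(k) 21 + 30 * (seq_len(k) - 1)))
  ) |>
    mutate(dispense_date = rep(truth$index_date, n_disp) - .data$offset) |>
    select(-"offset")
  n_part <- lengths(truth$partners)
  disp_partners <- tibble(
    patient_id = rep(truth$patient_id, n_part),
    atc_code = unlist(truth$partners),
    dispense_date = rep(truth$index_date, n_part) - 21
  )
  n_noise <- pmin(rpois(n, 2), length(NOISE_POOL))
  disp_noise <- tibble(
    patient_id = rep(truth$patient_id, n_noise),
    atc_code = unlist(lapply(n_noise, function(k) sample(NOISE_POOL, k))),
    dispense_date = rep(truth$index_date, n_noise) - 15
  )
  dispensing <- bind_rows(disp_anticoag, disp_partners, disp_noise) |>
    mutate(supply_days = config$supply_days) |>
    arrange(.data$patient_id, .data$dispense_date, .data$atc_code)

  # ---- stays ----------------------------------------------------------
  assoc <- purrr::pmap_chr(
    list(truth$stroke, truth$diabetes, truth$liver, truth$cancer,
         truth$hypertension, truth$renal),
    function(st, di, li, ca, hy, re) {
      codes <- c(COMORB_CODE[c("stroke", "diabetes", "liver", "cancer",
                               "hypertension")][c(st, di, li, ca, hy)],
                 if (re) "N189")
      if (length(codes) == 0) "" else paste0(codes, ":A", collapse = ";")
    }
  )
  principal <- ifelse(
    !is.na(truth$ade_criterion) & truth$ade_criterion == "diagnosis",
    sample(BLEED_DX_POOL, n, replace = TRUE), "I48"
  )
  index_stays <- tibble(
    patient_id = truth$patient_id,
    admission_date = truth$index_date,
    discharge_date = discharge,
    stay_type = truth$stay_type,
    icd10_codes = ifelse(assoc == "", paste0(principal, ":P"),
                         paste0(principal, ":P;", assoc))
  )
  pb <- which(truth$prev_bleed)
  pb_adm <- truth$index_date[pb] - sample(60:300, length(pb), replace = TRUE)
  bleed_prior <- tibble(
    patient_id = truth$patient_id[pb], admission_date = pb_adm,
    discharge_date = pb_adm + 3, stay_type = "medicine",
    icd10_codes = "K921:P"
  )
  n_prior <- rbinom(n, 2, 0.2)
  other_prior <- tibble(
    patient_id = rep(truth$patient_id, n_prior),
    admission_date = rep(truth$index_date, n_prior) -
      sample(40:330, sum(n_prior), replace = TRUE),
    stay_type = "medicine", icd10_codes = "I48:P"
  ) |>
    mutate(discharge_date = .data$admission_date + 2) |>
    relocate("discharge_date", .after = "admission_date")
  stays <- bind_rows(index_stays, bleed_prior, other_prior) |>
    arrange(.data$patient_id, .data$admission_date)

  # ---- administrations ------------------------------------------------
  adm_list <- list()
  cont <- which(truth$continued)
  if (length(cont) > 0) {
    adm_list$anticoag <- tibble(
      patient_id = rep(truth$patient_id[cont], each = 2),
      atc_code = rep(ANTICOAG_ATC[hosp_molecule[cont]], each = 2),
      admin_date = rep(truth$index_date[cont], each = 2) + c(1, 2)
    )
    readminister <- purrr::map(cont, function(i) {
      prt <- truth$partners[[i]]
      prt[runif(length(prt)) < 0.5]
    })
    k <- lengths(readminister)
    adm_list$partners <- tibble(
      patient_id = rep(truth$patient_id[cont], k),
      atc_code = unlist(readminister),
      admin_date = rep(truth$index_date[cont], k) + 1
    )
    parac <- cont[truth$molecule[cont] == "warfarin" & runif(length(cont)) < 0.7]
    adm_list$paracetamol <- tibble(
      patient_id = truth$patient_id[parac], atc_code = "N02BE01",
      admin_date = truth$index_date[parac] + 1
    )
    hep <- cont[truth$molecule[cont] != "warfarin" & runif(length(cont)) < 0.4]
    adm_list$heparin <- tibble(
      patient_id = truth$patient_id[hep], atc_code = "B01AB05",
      admin_date = truth$index_date[hep] + 1
    )
  }
  anti <- which(!is.na(truth$ade_criterion) & truth$ade_criterion == "antidote")
  if (length(anti) > 0) {
    adm_list$antidote <- tibble(
      patient_id = truth$patient_id[anti],
      atc_code = sample_pool(ANTIDOTE_POOL, length(anti)),
      admin_date = truth$index_date[anti] + 1
    )
  }

  # ---- labs -----------------------------------------------------------
  crit <- dplyr::coalesce(truth$ade_criterion, "none")
  hb_low <- ifelse(truth$sex == "M", runif(n, 8, 11), runif(n, 7, 10))
  hb_norm <- ifelse(truth$sex == "M", runif(n, 12, 16), runif(n, 11, 15))
  labs <- bind_rows(
    tibble(patient_id = truth$patient_id, date = truth$index_date - 45,
           analyte = "hemoglobin",
           value = ifelse(truth$sex == "M", runif(n, 13, 15.5),
                          runif(n, 12, 14.5))),
    tibble(patient_id = truth$patient_id, date = truth$index_date + 1,
           analyte = "hemoglobin",
           value = ifelse(crit == "hemoglobin", hb_low, hb_norm)),
    tibble(patient_id = truth$patient_id, date = truth$index_date + 1,
           analyte = "INR",
           value = ifelse(crit == "inr", runif(n, 5.5, 9),
                          runif(n, 1.5, 4))) |>
      filter(truth$molecule == "warfarin" | crit == "inr")
  ) |>
    mutate(value = round(.data$value, 1)) |>
    arrange(.data$patient_id, .data$date, .data$analyte)

  # ---- hospital-only initiators --------------------------------------
  n_init <- round(config$initiated_ratio * n)
  init <- NULL
  if (n_init > 0) {
    hosp_shares <- c(warfarin = 0.508, apixaban = 0.248, rivaroxaban = 0.192,
                     dabigatran = 0.073)
    init <- tibble(
      patient_id = sprintf("H%05d", seq_len(n_init)),
      molecule = sample(names(hosp_shares), n_init, replace = TRUE,
                        prob = hosp_shares),
      age = as.integer(floor(rtrunc_norm(n_init, config$age_mean,
                                         config$age_sd, config$age_min,
                                         config$age_max))),
      sex = ifelse(runif(n_init) < config$p_male, "M", "F"),
      index_date = config$start_date +
        floor(runif(n_init) *
                (as.numeric(config$end_date - config$start_date) + 1)),
      stay_type = ifelse(runif(n_init) < config$p_surgery, "surgery",
                         "medicine")
    )
    init_los <- sample(2:14, n_init, replace = TRUE)
    patients <- bind_rows(patients, tibble(
      patient_id = init$patient_id, sex = init$sex,
      birth_year_month = month_before(init$index_date, init$age),
      index_admission_date = init$index_date
    ))
    stays <- bind_rows(stays, tibble(
      patient_id = init$patient_id, admission_date = init$index_date,
      discharge_date = init$index_date + init_los,
      stay_type = init$stay_type, icd10_codes = "I48:P"
    ))
    adm_list$initiators <- tibble(
      patient_id = rep(init$patient_id, each = 2),
      atc_code = rep(ANTICOAG_ATC[init$molecule], each = 2),
      admin_date = rep(init$index_date, each = 2) + c(1, 2)
    )
    truth <- bind_rows(truth |> select(-"partners"), tibble(
      patient_id = init$patient_id, molecule = init$molecule,
      age = init$age, sex = init$sex, renal = FALSE,
      pim = NA, ddi = NA, pim_ddi = NA, ade = NA,
      pathway = "initiated_in_hospital", continued = NA,
      stay_type = init$stay_type, index_date = init$index_date,
      n_ddi_pairs = NA_integer_
    ))
  } else {
    truth <- truth |> select(-"partners")
  }
  administrations <- bind_rows(adm_list) |>
    arrange(.data$patient_id, .data$admin_date, .data$atc_code)

  structure(
    list(
      tables = list(patients = patients, dispensing = dispensing,
                    administrations = administrations, stays = stays,
                    labs = labs),
      truth = truth,
      config = config,
      intercept = intercept
    ),
    class = "pimddi_cohort"
  )
}

#' @export
print.pimddi_cohort <- function(x, ...) {
  cat("<pimddi synthetic cohort>\n")
  cat("  primary-care patients:", sum(grepl("^P", x$truth$patient_id)),
      " hospital-only initiators:", sum(grepl("^H", x$truth$patient_id)), "\n")
  cat("  planted: PIM", x$config$p_pim, " DDI", x$config$p_ddi,
      " PIM-DDI", x$config$p_pim_ddi, " ADE", x$config$target_ade_rate, "\n")
  invisible(x)
}

#' Write a synthetic cohort's tables to CSV files
#'
#' @param cohort a `pimddi_cohort` object
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kinds <- c(patients = "patients", dispensing = "dispensing",
             administrations = "administrations", stays = "stays",
             labs = "labs")
  for (nm in names(kinds)) {
    write_oac_table(validate_oac_table(cohort$tables[[nm]], kinds[[nm]]),
                    file.path(dir, paste0(nm, ".csv")), kinds[[nm]])
  }
  invisible(dir)
}
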