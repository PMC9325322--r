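# Builders for tiny in-memory cohorts and brute-force oracles used
# across the test files.

D0 <- as.Date("2016-06-15") # default index admission date

tiny_patient <- function(id = "p1", sex = "M", age = 80, index = D0) {
  tibble::tibble(
    patient_id = id, sex = sex,
    birth_year_month = as.Date(format(index - round(age * 365.25) - 40,
                                      "%Y-%m-01")),
    index_admission_date = index
  )
}

tiny_stay <- function(id = "p1", admission = D0, los = 7,
                      stay_type = "medicine", codes = "I48:P") {
  tibble::tibble(patient_id = id, admission_date = admission,
                 discharge_date = admission + los, stay_type = stay_type,
                 icd10_codes = codes)
}

tiny_dispensing <- function(id, atc, date, supply = 30) {
  tibble::tibble(patient_id = id, atc_code = atc, dispense_date = date,
                 supply_days = supply)
}

tiny_tables <- function(patients, dispensing = NULL, administrations = NULL,
                        stays = NULL, labs = NULL) {
  empty_disp <- tibble::tibble(patient_id = character(),
                               atc_code = character(),
                               dispense_date = as.Date(character()),
                               supply_days = integer())
  empty_adm <- tibble::tibble(patient_id = character(),
                              atc_code = character(),
                              admin_date = as.Date(character()))
  empty_labs <- tibble::tibble(patient_id = character(),
                               date = as.Date(character()),
                               analyte = character(), value = numeric())
  list(
    patients = patients,
    dispensing = dispensing %||% empty_disp,
    administrations = administrations %||% empty_adm,
    stays = stays %||% purrr::map_dfr(patients$patient_id, tiny_stay),
    labs = labs %||% empty_labs
  )
}

# day-set coverage oracle: all covered days per (patient, drug, setting)
oracle_coverage_days <- function(dispensings, administrations,
                                 supply_default = 30) {
  days <- list()
  add <- function(key, from, to) {
    days[[key]] <<- union(days[[key]], as.integer(seq(from, to, by = "day")))
  }
  if (!is.null(dispensings) && nrow(dispensings) > 0) {
    for (i in seq_len(nrow(dispensings))) {
      r <- dispensings[i, ]
      supply <- if (is.na(r$supply_days)) supply_default else r$supply_days
      add(paste(r$patient_id, r$atc_code, "primary_care", sep = "|"),
          r$dispense_date, r$dispense_date + supply)
    }
  }
  if (!is.null(administrations) && nrow(administrations) > 0) {
    for (i in seq_len(nrow(administrations))) {
      r <- administrations[i, ]
      add(paste(r$patient_id, r$atc_code, "hospital", sep = "|"),
          r$admin_date, r$admin_date)
    }
  }
  lapply(days, sort)
}

era_days <- function(eras) {
  out <- list()
  for (i in seq_len(nrow(eras))) {
    r <- eras[i, ]
    key <- paste(r$patient_id, r$atc_code, r$setting, sep = "|")
    out[[key]] <- union(out[[key]],
                        as.integer(seq(r$start, r$end, by = "day")))
  }
  lapply(out, sort)
}

# brute-force day-by-day co-exposure scan within each patient's setting
# window; returns one row per (patient, unordered interacting pair)
oracle_ddi_scan <- function(patients, stays, eras, kb, setting,
                            window_days = 30) {
  out <- list()
  for (pid in patients$patient_id) {
    idx <- patients$index_admission_date[patients$patient_id == pid]
    if (setting == "primary_care") {
      win <- seq(idx - window_days, idx - 1, by = "day")
    } else {
      st <- stays[stays$patient_id == pid & stays$admission_date == idx, ]
      if (nrow(st) == 0) next
      win <- seq(st$admission_date[1], st$discharge_date[1], by = "day")
    }
    e <- eras[eras$patient_id == pid & eras$setting == setting, ]
    if (nrow(e) < 2) next
    pairs <- character(0)
    for (day in as.list(win)) {
      drugs <- unique(e$atc_code[e$start <= day & e$end >= day])
      if (length(drugs) < 2) next
      cmb <- utils::combn(sort(drugs), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        hit <- any(vapply(seq_len(nrow(kb$interactions)), function(r) {
          rule <- kb$interactions[r, ]
          (match_atc(a, rule$drug_a_pattern) && match_atc(b, rule$drug_b_pattern)) ||
            (match_atc(b, rule$drug_a_pattern) && match_atc(a, rule$drug_b_pattern))
        }, logical(1)))
        if (hit) pairs <- union(pairs, paste(a, b, sep = "~"))
      }
    }
    if (length(pairs) > 0) {
      out[[pid]] <- tibble::tibble(patient_id = pid, pair = pairs)
    }
  }
  dplyr::bind_rows(out)
}

# exhaustive threshold-selection oracle over all observed cut-points
oracle_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  cands <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in cands) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (is.null(best) || d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(t = t, d = d, sens = sens, spec = spec)
    }
  }
  best
}
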