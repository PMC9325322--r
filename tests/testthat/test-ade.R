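# Bleeding-ADE phenotype: the four criteria and their composition.

kb <- load_kb()
bleed_set <- kb$code_sets$bleeding_icd10

test_that("the diagnosis criterion fires on bleeding codes only", {
  dx <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                       code = c("R31", "I48", "K921"))
  out <- detect_by_diagnosis(dx, bleed_set)
  expect_identical(out$fired, c(TRUE, FALSE, TRUE)) # hematuria, AF, melena
  expect_identical(out$evidence[1], "R31")
  # prefix matching on code roots
  out2 <- detect_by_diagnosis(tibble::tibble(patient_id = "p", code = "I610"),
                              bleed_set)
  expect_true(out2$fired)
})

test_that("the INR criterion is strictly greater than 5", {
  labs <- tibble::tibble(patient_id = c("p1", "p2"), date = D0,
                         analyte = "INR", value = c(5.6, 5.0))
  out <- detect_by_inr(labs)
  expect_identical(out$fired, c(TRUE, FALSE))
  expect_match(out$evidence[1], "INR 5.6")
  # no INR measurements at all: nothing fires
  none <- detect_by_inr(tibble::tibble(patient_id = character(),
                                       date = as.Date(character()),
                                       analyte = character(),
                                       value = numeric()))
  expect_identical(nrow(none), 0L)
})

test_that("hemoglobin thresholds are sex-specific and inclusive", {
  labs <- tibble::tibble(patient_id = c("m1", "f1", "f2"), date = D0,
                         analyte = "hemoglobin", value = c(10.8, 10.5, 10.0))
  sex <- tibble::tibble(patient_id = c("m1", "f1", "f2"),
                        sex = c("M", "F", "F"))
  out <- detect_by_hemoglobin(labs, sex)
  fired <- setNames(out$fired, out$patient_id)
  expect_identical(fired[c("m1", "f1", "f2")],
                   c(m1 = TRUE, f1 = FALSE, f2 = TRUE))
  expect_error(
    detect_by_hemoglobin(labs, tibble::tibble(patient_id = "m1", sex = "M")),
    "unknown sex"
  )
})

test_that("delta mode additionally requires a 2 g/dL drop from baseline", {
  labs <- tibble::tibble(patient_id = c("p1", "p2"), date = D0,
                         analyte = "hemoglobin", value = c(10.5, 10.5))
  sex <- tibble::tibble(patient_id = c("p1", "p2"), sex = "M")
  base <- tibble::tibble(patient_id = c("p1", "p2"), date = D0 - 40,
                         analyte = "hemoglobin", value = c(14.0, 11.5))
  out <- detect_by_hemoglobin(labs, sex, mode = "delta", baseline_labs = base)
  expect_identical(out$fired, c(TRUE, FALSE)) # p2 dropped only 1 g/dL
  expect_error(detect_by_hemoglobin(labs, sex, mode = "delta"), "baseline")
})

test_that("the antidote criterion fires on the four reversal agents", {
  adm <- tibble::tibble(patient_id = c("p1", "p2", "p3", "p3"),
                        atc_code = c("V03AB37", "B01AB01", "B02BA02",
                                     "B02BD01"),
                        admin_date = D0)
  out <- detect_by_antidote(adm, kb$code_sets$antidote_atc)
  expect_identical(out$fired, c(TRUE, FALSE, TRUE))
  expect_identical(out$evidence[3], "B02BA02,B02BD01") # all listed once
})

test_that("the composite equals the OR of the four criteria and is monotone", {
  set.seed(5)
  for (rep in 1:20) {
    has_dx <- runif(1) < 0.4
    has_inr <- runif(1) < 0.4
    has_hb <- runif(1) < 0.4
    has_anti <- runif(1) < 0.3
    p <- tiny_patient("p1", sex = "F", age = 78)
    stays <- tiny_stay("p1", codes = if (has_dx) "K921:P" else "I48:P")
    labs <- dplyr::bind_rows(
      tibble::tibble(patient_id = "p1", date = D0 + 1, analyte = "INR",
                     value = if (has_inr) 6.2 else 2.1),
      tibble::tibble(patient_id = "p1", date = D0 + 1,
                     analyte = "hemoglobin",
                     value = if (has_hb) 9.1 else 12.4)
    )
    adm <- if (has_anti) {
      tibble::tibble(patient_id = "p1", atc_code = "B02BA02",
                     admin_date = D0 + 1)
    } else {
      NULL
    }
    tbl <- tiny_tables(p, tiny_dispensing("p1", "B01AA03", D0 - 21),
                       administrations = adm, stays = stays, labs = labs)
    tbl <- purrr::imap(tbl, validate_oac_table)
    out <- detect_bleeding_ade(tbl$patients, tbl$stays, tbl$labs,
                               tbl$administrations, kb)
    expect_identical(out$is_ade, has_dx || has_inr || has_hb || has_anti)
    want <- paste(c("diagnosis", "inr", "hemoglobin", "antidote")[
      c(has_dx, has_inr, has_hb, has_anti)
    ], collapse = ",")
    expect_identical(out$criteria_fired, want)
  }
})

test_that("adding qualifying evidence never unsets the phenotype", {
  p <- tiny_patient("p1", sex = "M", age = 78)
  base_labs <- tibble::tibble(patient_id = "p1", date = D0 + 1,
                              analyte = "INR", value = 6.0)
  tbl <- tiny_tables(p, tiny_dispensing("p1", "B01AA03", D0 - 21),
                     labs = base_labs)
  tbl <- purrr::imap(tbl, validate_oac_table)
  out1 <- detect_bleeding_ade(tbl$patients, tbl$stays, tbl$labs,
                              tbl$administrations, kb)
  expect_true(out1$is_ade)
  # pile on a diagnosis, a low hemoglobin and an antidote
  tbl$stays$icd10_codes <- "R31:P"
  tbl$labs <- dplyr::bind_rows(
    tbl$labs, tibble::tibble(patient_id = "p1", date = D0 + 2,
                             analyte = "hemoglobin", value = 9.0)
  )
  tbl$administrations <- validate_oac_table(
    tibble::tibble(patient_id = "p1", atc_code = "V03AB38",
                   admin_date = D0 + 1),
    "administrations"
  )
  out2 <- detect_bleeding_ade(tbl$patients, tbl$stays, tbl$labs,
                              tbl$administrations, kb)
  expect_true(out2$is_ade)
  expect_identical(out2$criteria_fired, "diagnosis,inr,hemoglobin,antidote")
})

test_that("labs outside the stay window do not fire", {
  p <- tiny_patient("p1", sex = "M", age = 78)
  labs <- tibble::tibble(patient_id = "p1", date = D0 - 10, analyte = "INR",
                         value = 7.5) # pre-admission
  tbl <- tiny_tables(p, tiny_dispensing("p1", "B01AA03", D0 - 21),
                     labs = labs)
  tbl <- purrr::imap(tbl, validate_oac_table)
  out <- detect_bleeding_ade(tbl$patients, tbl$stays, tbl$labs,
                             tbl$administrations, kb)
  expect_false(out$is_ade)
  # widening the margin pulls it in
  out2 <- detect_bleeding_ade(tbl$patients, tbl$stays, tbl$labs,
                              tbl$administrations, kb, lab_margin_days = 15)
  expect_true(out2$is_ade)
})
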