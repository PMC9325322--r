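# Exposure windows, Beers PIM classification, DDI screening, PIM-DDI.

kb <- load_kb()

screen_tiny <- function(tables, ...) {
  suppressMessages(screen_cohort(tables, kb = kb, quiet = TRUE, ...))
}

test_that("pre-admission window exposure follows era intersection", {
  p <- tiny_patient("p1", age = 70)
  # dispensed 14 days pre-admission: inside the 30-day window
  t1 <- tiny_tables(p, tiny_dispensing("p1", "B01AF01", D0 - 14))
  e1 <- detect_anticoag_exposure(
    validate_oac_table(p, "patients"), validate_oac_table(t1$stays, "stays"),
    build_drug_eras(t1$dispensing), kb
  )
  expect_identical(e1$setting, "primary_care")
  expect_identical(e1$molecule, "rivaroxaban")

  # dispensed 45 days pre-admission with 30-day supply: the era END falls
  # in the window
  t2 <- tiny_tables(p, tiny_dispensing("p1", "B01AF01", D0 - 45))
  e2 <- detect_anticoag_exposure(
    validate_oac_table(p, "patients"), validate_oac_table(t2$stays, "stays"),
    build_drug_eras(t2$dispensing), kb
  )
  expect_identical(nrow(e2), 1L)

  # dispensed 80 days pre-admission: era exhausted before the window
  t3 <- tiny_tables(p, tiny_dispensing("p1", "B01AF01", D0 - 80))
  e3 <- detect_anticoag_exposure(
    validate_oac_table(p, "patients"), validate_oac_table(t3$stays, "stays"),
    build_drug_eras(t3$dispensing), kb
  )
  expect_identical(nrow(e3), 0L)

  # no anticoagulant records at all
  t4 <- tiny_tables(p, tiny_dispensing("p1", "N02BE01", D0 - 14))
  e4 <- detect_anticoag_exposure(
    validate_oac_table(p, "patients"), validate_oac_table(t4$stays, "stays"),
    build_drug_eras(t4$dispensing), kb
  )
  expect_identical(nrow(e4), 0L)
})

test_that("Beers PIM rules classify DOACs by age and renal status", {
  run_pim <- function(age, atc, codes = "I48:P", renal_override = NA) {
    p <- tiny_patient("p1", age = age)
    p$renal_override <- renal_override
    tbl <- tiny_tables(p, tiny_dispensing("p1", atc, D0 - 14),
                       stays = tiny_stay("p1", codes = codes))
    scr <- screen_tiny(tbl)
    scr$pim |> dplyr::filter(setting == "primary_care")
  }
  # dabigatran at 80: age rule
  expect_identical(run_pim(80, "B01AE07")$triggered_rule, "age_ge_75")
  # apixaban at 70 without renal impairment: no PIM
  expect_identical(nrow(run_pim(70, "B01AF02")), 0L)
  # apixaban at 70 with a coded renal diagnosis
  expect_identical(run_pim(70, "B01AF02", codes = "I48:P;N189:A")$triggered_rule,
                   "age_ge_65_renal")
  # rivaroxaban at 70 with the eGFR-based override column
  expect_identical(run_pim(70, "B01AF01", renal_override = TRUE)$triggered_rule,
                   "age_ge_65_renal")
  # rivaroxaban at 74 (below the age-alone threshold), no renal: none
  expect_identical(nrow(run_pim(74, "B01AF01")), 0L)
})

test_that("warfarin is PIM only through an overlapping Beers partner", {
  p <- tiny_patient("p1", age = 68)
  tbl <- tiny_tables(p, dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 10)
  ))
  scr <- screen_tiny(tbl)
  pim <- scr$pim |> dplyr::filter(setting == "primary_care")
  expect_identical(pim$triggered_rule, "warfarin_combo")
  expect_identical(pim$partner_atc, "C01BD01")

  # same partner era but no longer overlapping within the window
  tbl2 <- tiny_tables(p, dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 120)
  ))
  expect_identical(nrow(screen_tiny(tbl2)$pim), 0L)

  # a non-Beers co-medication does not make warfarin a PIM
  tbl3 <- tiny_tables(p, dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "N02BE01", D0 - 10)
  ))
  expect_identical(nrow(screen_tiny(tbl3)$pim), 0L)
})

test_that("DDI detection matches KB rules with severities and mechanisms", {
  p <- tiny_patient("p1", age = 70)
  tbl <- tiny_tables(p, dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "N02BE01", D0 - 10)
  ))
  ddi <- screen_tiny(tbl)$ddi |> dplyr::filter(setting == "primary_care")
  expect_identical(ddi$raw_theriaque_level, 3L)
  expect_identical(ddi$severity, "moderate")
  expect_identical(ddi$mechanism, "PD")

  tbl2 <- tiny_tables(tiny_patient("p1", age = 70), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AF01", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 10)
  ))
  ddi2 <- screen_tiny(tbl2)$ddi |> dplyr::filter(setting == "primary_care")
  expect_identical(ddi2$raw_theriaque_level, 2L)
  expect_identical(ddi2$mechanism, "PK_CYP3A4_PGP")

  # a single-drug patient has no interactions
  tbl3 <- tiny_tables(p, tiny_dispensing("p1", "B01AA03", D0 - 21))
  expect_identical(nrow(screen_tiny(tbl3)$ddi), 0L)
})

test_that("DDI detection is invariant to input record order", {
  p <- tiny_patient("p1", age = 80)
  disp <- dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 15),
    tiny_dispensing("p1", "N02BE01", D0 - 10),
    tiny_dispensing("p1", "C10AA05", D0 - 5)
  )
  a <- screen_tiny(tiny_tables(p, disp))$ddi
  b <- screen_tiny(tiny_tables(p, disp[sample(nrow(disp)), ]))$ddi
  expect_identical(a, b)
})

test_that("DDI detection equals a brute-force day-by-day co-exposure scan", {
  set.seed(99)
  drugs <- c("B01AA03", "B01AF01", "B01AE07", "C01BD01", "N02BE01",
             "N02AX02", "B01AC06", "C10AA05", "A10BA02", "J01FA10")
  for (rep in 1:5) {
    n_pat <- 8
    ids <- sprintf("p%02d", seq_len(n_pat))
    patients <- purrr::map_dfr(ids, function(id) {
      tiny_patient(id, age = sample(66:90, 1))
    })
    n <- 60
    disp <- tibble::tibble(
      patient_id = sample(ids, n, replace = TRUE),
      atc_code = sample(drugs, n, replace = TRUE),
      dispense_date = D0 - sample(1:80, n, replace = TRUE),
      supply_days = sample(c(7L, 30L), n, replace = TRUE)
    )
    stays <- purrr::map_dfr(ids, tiny_stay)
    pv <- validate_oac_table(patients, "patients")
    sv <- validate_oac_table(stays, "stays")
    eras <- build_drug_eras(validate_oac_table(disp, "dispensing"))
    got <- detect_ddi(pv, sv, eras, kb, setting = "primary_care") |>
      dplyr::mutate(pair = paste(pmin(drug_a_atc, drug_b_atc),
                                 pmax(drug_a_atc, drug_b_atc), sep = "~")) |>
      dplyr::select(patient_id, pair) |>
      dplyr::arrange(patient_id, pair)
    want <- oracle_ddi_scan(pv, sv, eras, kb, "primary_care")
    if (nrow(want) > 0) want <- dplyr::arrange(want, patient_id, pair)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("PIM-DDI flagging requires the anticoagulant member to be PIM", {
  # rivaroxaban at 80 (PIM by age) with amiodarone: PIM-DDI
  tbl <- tiny_tables(tiny_patient("p1", age = 80), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AF01", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 10)
  ))
  ddi <- screen_tiny(tbl)$ddi |> dplyr::filter(setting == "primary_care")
  expect_true(ddi$is_pim_ddi)

  # same pair at 70 without renal impairment: plain DDI
  tbl2 <- tiny_tables(tiny_patient("p1", age = 70), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AF01", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 10)
  ))
  ddi2 <- screen_tiny(tbl2)$ddi |> dplyr::filter(setting == "primary_care")
  expect_false(ddi2$is_pim_ddi)
})

test_that("a warfarin Beers combo spreads PIM-DDI to concurrent partners", {
  tbl <- tiny_tables(tiny_patient("p1", age = 68), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "C01BD01", D0 - 15),
    tiny_dispensing("p1", "N02BE01", D0 - 10)
  ))
  scr <- screen_tiny(tbl)
  ddi <- scr$ddi |> dplyr::filter(setting == "primary_care")
  expect_identical(nrow(ddi), 2L)
  expect_true(all(ddi$is_pim_ddi)) # paracetamol event flagged too
  expect_identical(dplyr::n_distinct(ddi$combo_id), 1L)
  lab <- label_combinations(ddi, scr$pim, kb)
  expect_true("warfarin-C01BD01-N02BE01" %in% lab$combination)
})

test_that("the azithromycin exclusion blocks the macrolide rule", {
  tbl <- tiny_tables(tiny_patient("p1", age = 68), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "J01FA10", D0 - 10)
  ))
  scr <- screen_tiny(tbl)
  expect_identical(nrow(scr$ddi), 0L)
  expect_identical(nrow(scr$pim), 0L)
  # any other macrolide triggers both
  tbl2 <- tiny_tables(tiny_patient("p1", age = 68), dplyr::bind_rows(
    tiny_dispensing("p1", "B01AA03", D0 - 21),
    tiny_dispensing("p1", "J01FA09", D0 - 10)
  ))
  scr2 <- screen_tiny(tbl2)
  expect_identical(nrow(scr2$ddi |> dplyr::filter(setting == "primary_care")),
                   1L)
  expect_true(all(scr2$ddi$is_pim_ddi[scr2$ddi$setting == "primary_care"]))
})

test_that("mechanism tabulation uses class and PK-subtype denominators", {
  # 3 PD patients, 2 PK patients of which 1 dual CYP3A4/P-gp
  ev <- tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e", "d"),
    setting = "primary_care",
    mechanism = c("PD", "PD", "PD", "PK_CYP2C9_2C19", "PK_CYP3A4_PGP",
                  "PK_CYP3A4_PGP")
  )
  tab <- tabulate_mechanisms(ev)
  cls <- tab |> dplyr::filter(level == "class")
  expect_identical(cls$n_patients[cls$mechanism == "PD"], 3L)
  expect_identical(cls$pct[cls$mechanism == "PD"], 60)
  expect_identical(cls$pct[cls$mechanism == "PK"], 40)
  sub <- tab |> dplyr::filter(level == "pk_subtype")
  expect_identical(sub$pct[sub$mechanism == "PK_CYP3A4_PGP"], 100)
  # all-PD event sets produce no PK subtype rows
  pd_only <- tabulate_mechanisms(ev |> dplyr::filter(mechanism == "PD"))
  expect_identical(nrow(pd_only |> dplyr::filter(level == "pk_subtype")), 0L)
})
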