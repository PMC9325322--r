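# ATC pattern matching, severity harmonization, knowledge-base loading.

test_that("ATC pattern matching honors prefixes, exclusions and exact codes", {
  expect_true(match_atc("J01FA09", "J01FA*!J01FA10"))
  expect_false(match_atc("J01FA10", "J01FA*!J01FA10")) # azithromycin excepted
  expect_true(match_atc("B01AA03", "B01AA03"))
  expect_false(match_atc("B01AA04", "B01AA03"))
  expect_true(match_atc(" b01aa03 ", "B01AA03")) # case/whitespace tolerant
  expect_true(all(match_atc(c("M01AE01", "M01AB05"), "M01A*")))
  expect_false(match_atc("M02AA01", "M01A*"))
  expect_error(match_atc("B01AA03", "B01AA"), "malformed")
  expect_error(match_atc("B01AA03", "1B*"), "malformed")
  expect_error(match_atc("B01AA", "B01AA03"), "not full ATC")
})

test_that("exact-code patterns reduce to string equality", {
  set.seed(11)
  codes <- replicate(50, paste0(
    sample(LETTERS, 1), sprintf("%02d", sample(0:99, 1)),
    paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
    sprintf("%02d", sample(0:99, 1))
  ))
  for (p in sample(codes, 10)) {
    expect_identical(match_atc(codes, p), codes == p)
  }
})

test_that("severity harmonization reproduces the full dual-source table", {
  # hand-written reference: rows Theriaque 1-4/absent, columns Micromedex
  ref <- tibble::tribble(
    ~th, ~mm, ~expected,
    1L, NA, "major", 2L, NA, "major", 3L, NA, "moderate", 4L, NA, "minor",
    1L, "contraindicated", "major", 1L, "major", "major",
    1L, "moderate", "major",
    2L, "contraindicated", "major", 2L, "major", "major",
    2L, "moderate", "major",
    3L, "contraindicated", "major", 3L, "major", "major",
    3L, "moderate", "moderate",
    4L, "contraindicated", "major", 4L, "major", "major",
    4L, "moderate", "moderate",
    NA, "contraindicated", "major", NA, "major", "major",
    NA, "moderate", "moderate"
  )
  for (i in seq_len(nrow(ref))) {
    expect_identical(harmonize_severity(ref$th[i], ref$mm[i]),
                     ref$expected[i],
                     info = paste("th", ref$th[i], "mm", ref$mm[i]))
  }
  expect_error(harmonize_severity(NA, NA), "at least one")
  expect_error(harmonize_severity(5, NA), "1:4")
  expect_error(harmonize_severity(NA, "severe"), "Micromedex")
})

test_that("harmonization is monotone: upgrading a source never lowers the class", {
  rank <- function(x) match(x, c("minor", "moderate", "major"))
  th_levels <- list(4L, 3L, 2L, 1L) # increasing severity
  mm_levels <- list("moderate", "major", "contraindicated")
  for (mm in c(list(NA_character_), mm_levels)) {
    out <- vapply(th_levels, function(t) harmonize_severity(t, mm), character(1))
    expect_true(all(diff(rank(out)) >= 0))
  }
  for (th in c(list(NA_integer_), th_levels)) {
    out <- vapply(mm_levels, function(m) harmonize_severity(th, m), character(1))
    expect_true(all(diff(rank(out)) >= 0))
  }
})

test_that("the shipped mini-KB loads cleanly and carries the expected content", {
  kb <- load_kb()
  expect_s3_class(kb, "pimddi_kb")
  expect_identical(nrow(kb$rejected), 0L)
  expect_setequal(kb$code_sets$antidote_atc,
                  c("B02BA02", "V03AB37", "V03AB38", "B02BD01"))
  # the flagship pair: rivaroxaban-amiodarone, level 2, dual CYP3A4/P-gp
  ra <- kb$interactions |>
    dplyr::filter(drug_a_pattern == "B01AF01", drug_b_pattern == "C01BD01")
  expect_identical(nrow(ra), 1L)
  expect_identical(ra$severity_theriaque, 2L)
  expect_identical(ra$mechanism, "PK_CYP3A4_PGP")
  expect_identical(ra$severity, "major")
  # every top-combination pair is covered (molecule ATC ~ partner ATC)
  must_have <- tibble::tribble(
    ~a, ~b,
    "B01AF01", "B01AC06", "B01AA03", "B01AC06", "B01AF01", "C01BD01",
    "B01AA03", "C01BD01", "B01AA03", "N02BE01", "B01AA03", "C10AA05",
    "B01AA03", "H03AA01", "B01AA03", "N02AX02", "B01AF01", "N02AX02"
  )
  keys <- paste(kb$interactions$drug_a_pattern, kb$interactions$drug_b_pattern)
  expect_true(all(paste(must_have$a, must_have$b) %in% keys))
})

test_that("invalid KB rules are rejected record-wise, not fatally", {
  tmp <- withr::local_tempfile(fileext = ".json")
  bad_kb <- list(
    schema_version = 1,
    interactions = list(
      list(drug_a = "B01AA03", drug_b = "C01BD01", severity_theriaque = 3,
           mechanism = "PD", bleeding_risk = TRUE),
      list(drug_a = "B01AA03", drug_b = "X99XX99", mechanism = "PD",
           bleeding_risk = TRUE), # no severity from either source
      list(drug_a = "C01BD01", drug_b = "B01AA03", severity_theriaque = 2,
           mechanism = "PD", bleeding_risk = TRUE), # duplicate unordered pair
      list(drug_a = "BAD", drug_b = "B01AA03", severity_theriaque = 2,
           mechanism = "PD", bleeding_risk = TRUE) # malformed pattern
    ),
    pim_rules = list(list(anticoag_atc = "B01AA03", min_age_alone = 75)),
    code_sets = list(bleeding_icd10 = "R31", antidote_atc = "B02BA02",
                     anticoagulant_atc = "B01AA03",
                     renal_impairment_icd10 = "N18")
  )
  jsonlite::write_json(bad_kb, tmp, auto_unbox = TRUE, null = "null")
  kb <- load_kb(tmp)
  expect_identical(nrow(kb$interactions), 1L)
  expect_identical(nrow(kb$rejected), 3L)
  expect_setequal(kb$rejected$reason,
                  c("severity absent from both sources",
                    "duplicate unordered pair", "invalid ATC pattern"))
  expect_identical(nrow(kb_validate(tmp)), 3L)
})
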