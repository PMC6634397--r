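# Rule engine for the operational misuse definition.

mk_tables <- function(f) pheno_case_tables(f)

base_case <- function(...) {
  f <- list(transfer = FALSE, age = 40L, included_service = TRUE,
            has_uds = TRUE, opiate = FALSE, cocaine = FALSE, pcp = FALSE,
            benzo = FALSE, amph = FALSE, adm_opioid = FALSE,
            adm_benzo = FALSE, adm_amph = FALSE, disp_before = FALSE,
            disp_after = FALSE, icd_misuse = FALSE)
  modifyList(f, list(...))
}

eval_case <- function(f) {
  tb <- mk_tables(f)
  evaluate_encounter(tb$encounters, tb$uds, tb$medications, tb$diagnoses)
}

test_that("criterion 1: opiate plus polysubstance flags", {
  expect_true(eval_case(base_case(opiate = TRUE, cocaine = TRUE))$criterion1)
  expect_true(eval_case(base_case(opiate = TRUE, pcp = TRUE))$criterion1)
  expect_true(eval_case(base_case(opiate = TRUE, benzo = TRUE))$criterion1)
  # explained benzo does not count as polysubstance
  expect_false(eval_case(base_case(opiate = TRUE, benzo = TRUE,
                                   adm_benzo = TRUE))$criterion1)
  expect_true(eval_case(base_case(opiate = TRUE, amph = TRUE))$criterion1)
  expect_false(eval_case(base_case(opiate = TRUE, amph = TRUE,
                                   adm_amph = TRUE))$criterion1)
  # cocaine alone without opiate is not criterion 1
  expect_false(eval_case(base_case(cocaine = TRUE))$criterion1)
})

test_that("criterion 2: opiate positive without admission opioid", {
  r <- eval_case(base_case(opiate = TRUE))
  expect_true(r$criterion2)
  expect_true(r$is_misuse)
  # admission opioid explains the positive
  r2 <- eval_case(base_case(opiate = TRUE, adm_opioid = TRUE))
  expect_false(r2$criterion2)
  expect_false(r2$is_misuse)
  # inpatient dispensing after the order does not explain the positive
  r3 <- eval_case(base_case(opiate = TRUE, disp_after = TRUE))
  expect_true(r3$criterion2)
})

test_that("criterion 3: misuse diagnosis code flags without any UDS", {
  r <- eval_case(base_case(has_uds = FALSE, icd_misuse = TRUE))
  expect_true(r$criterion3)
  expect_true(r$is_misuse)
})

test_that("panel eligibility: pre-order dispensing voids the panel", {
  r <- eval_case(base_case(opiate = TRUE, cocaine = TRUE, disp_before = TRUE))
  expect_false(r$criterion1)
  expect_false(r$criterion2)
  expect_false(r$is_misuse)
  expect_equal(r$eligible_uds_ids, "")
  # but criterion 3 is unaffected by panel eligibility
  r2 <- eval_case(base_case(opiate = TRUE, disp_before = TRUE,
                            icd_misuse = TRUE))
  expect_true(r2$is_misuse)
})

test_that("a dispense exactly at the order time voids the panel", {
  tb <- mk_tables(base_case(opiate = TRUE))
  tb$medications <- rbind(tb$medications, data.frame(
    encounter_id = 1L, drug_class = "opioid", source = "inpatient_dispense",
    event_time = 10, stringsAsFactors = FALSE))   # order_time is 10
  r <- evaluate_encounter(tb$encounters, tb$uds, tb$medications,
                          tb$diagnoses)
  expect_false(r$is_misuse)
})

test_that("exclusions: transfer, pediatric, non-ED/inpatient", {
  r <- eval_case(base_case(opiate = TRUE, transfer = TRUE))
  expect_false(r$is_misuse)
  expect_equal(r$exclusion_reason, "transfer")
  r2 <- eval_case(base_case(opiate = TRUE, age = 10L))
  expect_false(r2$is_misuse)
  expect_equal(r2$exclusion_reason, "pediatric")
  r3 <- eval_case(base_case(opiate = TRUE, included_service = FALSE))
  expect_false(r3$is_misuse)
  expect_equal(r3$exclusion_reason, "not_ed_or_inpatient")
})

test_that("exhaustive truth-table oracle over the full micro-universe", {
  uni <- pheno_universe()
  n <- nrow(uni)
  # assemble one big multi-encounter universe for the vectorized engine
  encs <- uds <- meds <- dxs <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- mk_tables(as.list(uni[i, ]))
    tb$encounters$encounter_id <- i
    tb$uds$encounter_id <- rep(i, nrow(tb$uds))
    tb$uds$uds_id <- rep(i, nrow(tb$uds))
    tb$medications$encounter_id <- rep(i, nrow(tb$medications))
    tb$diagnoses$encounter_id <- rep(i, nrow(tb$diagnoses))
    encs[[i]] <- tb$encounters; uds[[i]] <- tb$uds
    meds[[i]] <- tb$medications; dxs[[i]] <- tb$diagnoses
  }
  ev <- evaluate_encounters(do.call(rbind, encs), do.call(rbind, uds),
                            do.call(rbind, meds), do.call(rbind, dxs))
  want <- vapply(seq_len(n), function(i) oracle_misuse(as.list(uni[i, ])),
                 logical(1))
  expect_equal(ev$is_misuse, want)

  # scalar evaluator agrees with the vectorized one on a fixed subsample
  set.seed(1)
  for (i in sample.int(n, 200)) {
    tb <- mk_tables(as.list(uni[i, ]))
    r <- evaluate_encounter(tb$encounters, tb$uds, tb$medications,
                            tb$diagnoses)
    expect_equal(r$is_misuse, want[i], info = paste("case", i))
  }
})

test_that("adding a second eligible flagging panel never unflags", {
  f <- base_case(opiate = TRUE)
  tb <- mk_tables(f)
  r1 <- evaluate_encounter(tb$encounters, tb$uds, tb$medications,
                           tb$diagnoses)
  tb$uds <- rbind(tb$uds, transform(tb$uds, uds_id = 2L, order_time = 20))
  r2 <- evaluate_encounter(tb$encounters, tb$uds, tb$medications,
                           tb$diagnoses)
  expect_true(r1$is_misuse)
  expect_true(r2$is_misuse)
  expect_equal(r2$eligible_uds_ids, "1;2")
})

test_that("evaluation is idempotent", {
  cohort <- generate_cohort(cohort_config(n_encounters = 2000L, seed = 9L))
  a <- evaluate_encounters(cohort$encounters, cohort$uds,
                           cohort$medications, cohort$diagnoses)
  b <- evaluate_encounters(cohort$encounters, cohort$uds,
                           cohort$medications, cohort$diagnoses)
  expect_identical(a, b)
})

test_that("malformed inputs error clearly", {
  tb <- mk_tables(base_case(opiate = TRUE))
  bad_uds <- tb$uds
  bad_uds$encounter_id <- 99L
  expect_error(
    evaluate_encounters(tb$encounters, bad_uds, tb$medications, tb$diagnoses),
    "unknown encounter")
  bad_med <- data.frame(encounter_id = 1L, drug_class = "opioid",
                        source = "inpatient_dispense", event_time = NA_real_,
                        stringsAsFactors = FALSE)
  expect_error(
    evaluate_encounters(tb$encounters, tb$uds, bad_med, tb$diagnoses),
    "without event_time")
  bad_src <- bad_med
  bad_src$source <- "pharmacy"
  bad_src$event_time <- 1
  expect_error(
    evaluate_encounters(tb$encounters, tb$uds, bad_src, tb$diagnoses),
    "source")
  expect_error(criterion_icd(tb$diagnoses, registry = list()),
               "unknown code-set tag")
})

test_that("build_cohort patient mode keeps the latest misuse encounter", {
  ev <- data.frame(
    encounter_id = 1:5,
    eligible_uds_ids = "",
    criterion1 = FALSE, criterion2 = FALSE,
    criterion3 = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    is_misuse = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    exclusion_reason = NA_character_, stringsAsFactors = FALSE)
  enc <- data.frame(encounter_id = 1:5,
                    patient_id = c(1L, 1L, 1L, 2L, 2L),
                    admit_time = c(10, 50, 70, 30, 20))
  full <- build_cohort(ev, enc, mode = "encounter_level")
  expect_equal(full$encounter_id, c(1L, 2L, 4L, 5L))
  pat <- build_cohort(ev, enc, mode = "patient_level")
  expect_equal(pat$encounter_id, c(2L, 4L))
  # patient-level is always a subset of encounter-level
  expect_true(all(pat$encounter_id %in% full$encounter_id))
})

test_that("indicator matrix reconstructs the generator's indicator draws", {
  cohort <- generate_cohort(cohort_config(n_encounters = 60000L, seed = 13L))
  gt <- ground_truth_table(cohort)
  ids <- gt$encounter_id[gt$true_misuse]
  ind <- build_indicator_matrix(ids, cohort$encounters, cohort$uds,
                                cohort$medications, cohort$diagnoses)
  expect_identical(unname(ind), unname(cohort$indicators))
  expect_equal(rownames(ind), as.character(ids))
})

test_that("untested encounters score level 1 on all UDS items", {
  enc <- data.frame(
    encounter_id = 1L, patient_id = 1L, age_years = 30L, admit_time = 0,
    discharge_time = 50, first_vital_time = 1, naloxone_time = NA_real_,
    service = "medicine", is_transfer = FALSE, disposition = "home",
    elixhauser_score = 0, sex = "male", race = "white",
    insurance = "private", stringsAsFactors = FALSE)
  empty <- pheno_case_tables(base_case(has_uds = FALSE))
  ind <- build_indicator_matrix(1L, enc, empty$uds, empty$medications,
                                empty$diagnoses)
  expect_equal(unname(ind[1, c("uds_opiate_unexpl", "uds_cocaine",
                               "uds_benzo_unexpl")]),
               c(1L, 1L, 1L))
  expect_equal(unname(ind[1, "age_band"]), 2L)  # age 30 -> band 2
})

test_that("code registry round-trips through JSON", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(default_code_registry(), path)
  reg <- read_code_registry(path)
  expect_equal(reg, default_code_registry())
})
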