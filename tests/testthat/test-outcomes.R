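# Readmission rules, dispositions, and class comparisons.

enc_row <- function(id, pid, admit_h, disch_h, disposition = "home",
                    naloxone = NA_real_, vital = admit_h + 1) {
  data.frame(encounter_id = id, patient_id = pid, admit_time = admit_h,
             discharge_time = disch_h, first_vital_time = vital,
             naloxone_time = naloxone, disposition = disposition,
             stringsAsFactors = FALSE)
}

no_dx <- data.frame(encounter_id = integer(), code = character(),
                    stringsAsFactors = FALSE)

test_that("index eligibility excludes death, late discharge, planned", {
  enc <- rbind(
    enc_row(1L, 1L, 0, 24),
    enc_row(2L, 2L, 0, 24, disposition = "death"),
    enc_row(3L, 3L, 0, 80 * 24),            # discharge day 80 > 100 - 30
    enc_row(4L, 4L, 0, 24)                  # planned tag below
  )
  dx <- data.frame(encounter_id = 4L, code = "PL001",
                   stringsAsFactors = FALSE)
  expect_equal(eligible_index(enc, dx, study_end_day = 100),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(eligible_index(enc[0, ], no_dx), logical(0))
})

test_that("window boundaries: day 30 counts, day 31 and same day do not", {
  mk <- function(day2) rbind(enc_row(1L, 1L, 0, 10),
                             enc_row(2L, 1L, day2 * 24 + 2, day2 * 24 + 8))
  f30 <- flag_unplanned_readmission_30d(mk(30), no_dx, study_end_day = 100)
  expect_true(f30$readmitted_30d[1])
  expect_equal(f30$triggering_encounter_id[1], 2L)
  f31 <- flag_unplanned_readmission_30d(mk(31), no_dx, study_end_day = 100)
  expect_false(f31$readmitted_30d[1])
  f0 <- flag_unplanned_readmission_30d(
    rbind(enc_row(1L, 1L, 0, 10), enc_row(2L, 1L, 12, 20)), no_dx,
    study_end_day = 100)
  expect_false(f0$readmitted_30d[1])       # same calendar day ignored
})

test_that("planned readmission suppresses, later unplanned not counted", {
  enc <- rbind(enc_row(1L, 1L, 0, 10),
               enc_row(2L, 1L, 5 * 24, 5 * 24 + 10),     # planned, day 5
               enc_row(3L, 1L, 20 * 24, 20 * 24 + 10))   # unplanned, day 20
  dx <- data.frame(encounter_id = 2L, code = "PL002",
                   stringsAsFactors = FALSE)
  f <- flag_unplanned_readmission_30d(enc, dx, study_end_day = 100)
  expect_false(f$readmitted_30d[1])
  # the planned encounter is itself ineligible as an index, but the
  # unplanned day-20 one can seed its own outcome chain
  expect_false(f$eligible_index[2])
})

test_that("at most one outcome per index", {
  enc <- rbind(enc_row(1L, 1L, 0, 10),
               enc_row(2L, 1L, 5 * 24, 5 * 24 + 10),
               enc_row(3L, 1L, 10 * 24, 10 * 24 + 10))
  f <- flag_unplanned_readmission_30d(enc, no_dx, study_end_day = 100)
  expect_equal(sum(f$readmitted_30d[1]), 1)
  expect_equal(f$triggering_encounter_id[1], 2L)
})

test_that("overlapping encounters for a patient raise an error", {
  enc <- rbind(enc_row(1L, 1L, 0, 50), enc_row(2L, 1L, 40, 90))
  expect_error(flag_unplanned_readmission_30d(enc, no_dx, 100),
               "overlapping")
})

test_that("exhaustive sequence oracle over short admission histories", {
  days <- c(0L, 1L, 5L, 10L, 20L, 29L, 30L, 31L, 45L)
  seqs <- list()
  for (len in 1:4) {
    combs <- do.call(expand.grid, rep(list(seq_along(days)), len))
    keep <- rep(TRUE, nrow(combs))
    if (len > 1) {
      for (j in 2:len) keep <- keep & combs[, j] >= combs[, j - 1]
    }
    combs <- combs[keep, , drop = FALSE]
    planned_sets <- do.call(expand.grid, rep(list(c(FALSE, TRUE)), len))
    for (a in seq_len(nrow(combs))) {
      for (p in seq_len(nrow(planned_sets))) {
        seqs[[length(seqs) + 1L]] <- list(
          days = days[as.integer(combs[a, ])],
          planned = as.logical(planned_sets[p, ]))
      }
    }
  }
  # one patient per case, all in a single call to the engine
  encs <- vector("list", length(seqs))
  dxs <- vector("list", length(seqs))
  next_id <- 0L
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    k <- length(s$days)
    ids <- next_id + seq_len(k)
    next_id <- next_id + k
    # stagger hours within a day so repeats never overlap
    admit <- s$days * 24 + seq_len(k)
    encs[[i]] <- data.frame(
      encounter_id = ids, patient_id = i, admit_time = admit,
      discharge_time = admit + 0.5, disposition = "home",
      stringsAsFactors = FALSE)
    if (any(s$planned)) {
      dxs[[i]] <- data.frame(encounter_id = ids[s$planned], code = "PL001",
                             stringsAsFactors = FALSE)
    }
  }
  enc <- do.call(rbind, encs)
  dx <- do.call(rbind, dxs)
  f <- flag_unplanned_readmission_30d(enc, dx, study_end_day = 100)
  got <- split(f$readmitted_30d, enc$patient_id)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    want <- oracle_readmit(s$days, s$planned, eligible = !s$planned)
    expect_equal(unname(got[[as.character(i)]]), want,
                 info = paste("case", i, paste(s$days, collapse = ","),
                              paste(s$planned, collapse = ",")))
  }
})

test_that("naloxone early flag is inclusive at three hours", {
  enc <- rbind(
    enc_row(1L, 1L, 0, 24, naloxone = 4, vital = 1),    # dt = 3 -> TRUE
    enc_row(2L, 2L, 0, 24, naloxone = 4.1, vital = 1),  # dt = 3.1 -> FALSE
    enc_row(3L, 3L, 0, 24)                              # none -> FALSE
  )
  expect_equal(naloxone_early_flag(enc), c(TRUE, FALSE, FALSE))
  pre <- enc_row(4L, 4L, 0, 24, naloxone = 0.5, vital = 1)
  expect_warning(flag <- naloxone_early_flag(pre), "before first")
  expect_true(flag)
})

test_that("outcome table arithmetic", {
  enc <- rbind(
    enc_row(1L, 1L, 0, 10, disposition = "home"),
    enc_row(2L, 2L, 0, 10, disposition = "ama"),
    enc_row(3L, 3L, 0, 10, disposition = "home"),
    enc_row(4L, 4L, 0, 10, disposition = "death")
  )
  labels <- c(1L, 1L, 2L, 2L)
  re <- data.frame(encounter_id = 1:4,
                   eligible_index = c(TRUE, TRUE, TRUE, FALSE),
                   readmitted_30d = c(TRUE, FALSE, FALSE, FALSE),
                   triggering_encounter_id = c(9L, NA, NA, NA))
  tab <- outcome_table(enc, labels, re)
  expect_equal(tab["class1", "n"], 2)
  expect_equal(tab["class1", "ama_pct"], 50)
  expect_equal(tab["class2", "death_pct"], 50)
  expect_equal(tab["class1", "readmission_pct"], 50)    # 1 of 2 eligible
  expect_equal(tab["class2", "readmission_pct"], 0)     # 0 of 1 eligible
  expect_equal(tab["overall", "eligible_index_n"], 3)
  expect_equal(tab["overall", "readmission_pct"], 100 / 3)
  expect_error(outcome_table(enc, labels[1:2]), "labels")
})

test_that("chi-square comparisons match stats::chisq.test", {
  events <- c(30, 10, 25, 5)
  totals <- c(100, 80, 90, 60)
  res <- compare_classes(events, totals)
  ref <- chisq.test(rbind(events, totals - events), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
  expect_equal(res$df, 3)

  one <- compare_classes(events, totals, comparison = "one_vs_rest",
                         class = 2)
  tab <- rbind(c(10, sum(events[-2])), c(70, sum(totals[-2] - events[-2])))
  ref2 <- chisq.test(t(tab), correct = FALSE)
  expect_equal(one$p_value, unname(ref2$p.value))
  expect_error(compare_classes(events, totals, comparison = "one_vs_rest"),
               "class index")
  # Yates correction passes through
  yates <- compare_classes(events, totals, comparison = "one_vs_rest",
                           class = 2, correct = TRUE)
  expect_lt(yates$statistic, one$statistic)
  # tiny expected counts produce a warning field
  small <- compare_classes(c(0, 1), c(2, 2))
  expect_match(small$warning, "below 1")
})

test_that("published outcome counts are significant at 0.01", {
  # class-1 readmission vs rest: 309/2270 eligible-index readmissions
  # against 416/3954 in the pooled other classes
  r1 <- compare_classes(c(309, 416), c(2270, 3954))
  expect_lt(r1$p_value, 0.01)
  # class-2 AMA vs rest: 98/798 against 288/5426
  r2 <- compare_classes(c(98, 288), c(798, 5426))
  expect_lt(r2$p_value, 0.01)
})

test_that("simulate_class_outcomes plants outcomes at the class rates", {
  set.seed(1)
  classes <- sample(1:4, 20000, TRUE)
  oc <- simulate_class_outcomes(classes, seed = 99)
  f <- flag_unplanned_readmission_30d(oc$encounters, oc$diagnoses,
                                      oc$study_end_day)
  idx <- f[oc$index_ids, ]
  rates <- calibrated_outcome_rates()
  for (cl in 1:4) {
    sel <- classes == cl
    p <- rates$readmission[cl]
    obs <- sum(idx$readmitted_30d[sel]) / sum(idx$eligible_index[sel])
    se <- sqrt(p * (1 - p) / sum(idx$eligible_index[sel]))
    expect_lt(abs(obs - p), 3 * se)
    disp <- oc$encounters$disposition[oc$index_ids][sel]
    for (d in c("ama", "death")) {
      pd <- rates$disposition[cl, d]
      se_d <- sqrt(pd * (1 - pd) / sum(sel))
      expect_lt(abs(mean(disp == d) - pd), 3 * se_d)
    }
  }
})
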