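# 30-day unplanned readmission flagging (CMS-style index/readmission rules),
# discharge-disposition tabulation, and class-wise comparisons.
#
# Day conventions: calendar day = floor(time_in_hours / 24); a readmission
# counts iff 0 < admit_day - index_discharge_day <= 30 (same calendar day
# never counts); in-window admissions are scanned chronologically and a
# planned readmission encountered first suppresses the outcome; at most one
# outcome per eligible index.

encounter_day <- function(hours) floor(hours / 24)

planned_flags <- function(encounters, diagnoses,
                          registry = default_code_registry()) {
  codes <- registry_codes(registry, "planned_readmission")
  encounters$encounter_id %in%
    diagnoses$encounter_id[diagnoses$code %in% codes]
}

#' Index-admission eligibility
#'
#' An encounter is an eligible index admission unless it ended in in-hospital
#' death, was discharged within 30 days of the study end (incomplete
#' follow-up), or is itself a planned readmission.
#'
#' @param encounters encounter table
#' @param diagnoses diagnosis table (planned-readmission tags)
#' @param study_end_day last study day; defaults to the latest discharge day
#' @param registry code-set registry
#' @return logical vector along `encounters`
#' @export
eligible_index <- function(encounters, diagnoses,
                           study_end_day = NULL,
                           registry = default_code_registry()) {
  if (!nrow(encounters)) return(logical(0))
  disch_day <- encounter_day(encounters$discharge_time)
  study_end_day <- study_end_day %||% max(disch_day)
  !(encounters$disposition == "death") &
    (disch_day <= study_end_day - 30) &
    !planned_flags(encounters, diagnoses, registry)
}

#' Flag 30-day unplanned readmissions
#'
#' For every eligible index admission, scans the patient's subsequent
#' admissions in chronological order: the first admission with
#' `0 < admit_day - discharge_day <= 30` decides the outcome — unplanned
#' flags the index (once), planned suppresses it; same-calendar-day
#' admissions are ignored.
#'
#' @param encounters encounter table (all encounters, including any planted
#'   future admissions)
#' @param diagnoses diagnosis table
#' @param study_end_day last study day (defaults to latest discharge day)
#' @param registry code-set registry
#' @return data.frame with `encounter_id`, `eligible_index`,
#'   `readmitted_30d`, `triggering_encounter_id` (`NA` when not readmitted)
#' @export
flag_unplanned_readmission_30d <- function(encounters, diagnoses,
                                           study_end_day = NULL,
                                           registry = default_code_registry()) {
  n <- nrow(encounters)
  out <- data.frame(
    encounter_id = encounters$encounter_id,
    eligible_index = eligible_index(encounters, diagnoses, study_end_day,
                                    registry),
    readmitted_30d = rep(FALSE, n),
    triggering_encounter_id = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  if (!n) return(out)
  planned <- planned_flags(encounters, diagnoses, registry)
  ord <- order(encounters$patient_id, encounters$admit_time,
               encounters$encounter_id)
  pid <- encounters$patient_id[ord]
  adm_day <- encounter_day(encounters$admit_time)[ord]
  dis_day <- encounter_day(encounters$discharge_time)[ord]
  adm_t <- encounters$admit_time[ord]
  dis_t <- encounters$discharge_time[ord]
  pl <- planned[ord]
  elig <- out$eligible_index[ord]
  eid <- encounters$encounter_id[ord]

  same <- which(pid[-1] == pid[-length(pid)])
  if (any(adm_t[same + 1] < dis_t[same])) {
    bad <- unique(pid[same[adm_t[same + 1] < dis_t[same]]])
    stop("overlapping encounters for patient(s): ",
         paste(head(bad, 10), collapse = ", "))
  }

  flagged <- logical(length(ord))
  trig <- rep(NA_integer_, length(ord))
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1] - 1L, length(pid))
  for (g in seq_along(starts)) {
    idx <- starts[g]:ends[g]
    if (length(idx) < 2L) next
    for (i in seq_along(idx)[-length(idx)]) {
      ii <- idx[i]
      if (!elig[ii]) next
      for (j in (i + 1L):length(idx)) {
        jj <- idx[j]
        delta <- adm_day[jj] - dis_day[ii]
        if (delta <= 0) next           # same calendar day: ignored
        if (delta > 30) break
        if (pl[jj]) break              # planned first: outcome suppressed
        flagged[ii] <- TRUE
        trig[ii] <- eid[jj]
        break                          # at most one outcome per index
      }
    }
  }
  out$readmitted_30d[ord] <- flagged
  out$triggering_encounter_id[ord] <- trig
  stopifnot(all(!out$readmitted_30d | out$eligible_index))
  out
}

#' Early naloxone flag
#'
#' True iff naloxone was given no later than three hours (inclusive) after
#' the first recorded vital sign; administration before the first vital sign
#' still flags, with a warning (pre-triage dosing).
#'
#' @param encounters encounter table with `naloxone_time`, `first_vital_time`
#' @return logical vector
#' @export
naloxone_early_flag <- function(encounters) {
  dt <- encounters$naloxone_time - encounters$first_vital_time
  if (any(dt < 0, na.rm = TRUE)) {
    warning("naloxone before first recorded vital sign for encounter(s): ",
            paste(encounters$encounter_id[which(dt < 0)], collapse = ", "))
  }
  !is.na(dt) & dt <= 3
}

#' Per-class outcome table
#'
#' Counts and percentages of discharge dispositions per class plus 30-day
#' unplanned readmission (reported over eligible index encounters and, for
#' reference, over all encounters), with an overall column.
#'
#' @param encounters encounter rows of the analysis cohort
#' @param class_labels integer class per cohort encounter
#' @param readmission [flag_unplanned_readmission_30d()] rows for the same
#'   encounters (optional; readmission columns omitted when `NULL`)
#' @return data.frame of class `outcome_table`, one row per class plus
#'   `overall`
#' @export
outcome_table <- function(encounters, class_labels, readmission = NULL) {
  if (nrow(encounters) != length(class_labels)) {
    stop("class labels do not match the cohort rows")
  }
  dispositions <- c("home", "psychiatric", "ama", "death", "other")
  classes <- sort(unique(class_labels))
  groups <- c(as.list(classes), list(classes))
  rows <- lapply(groups, function(g) {
    sel <- class_labels %in% g
    n <- sum(sel)
    row <- list(n = n)
    for (d in dispositions) {
      cnt <- sum(encounters$disposition[sel] == d)
      row[[paste0(d, "_n")]] <- cnt
      row[[paste0(d, "_pct")]] <- if (n) 100 * cnt / n else NA_real_
    }
    if (!is.null(readmission)) {
      k <- match(encounters$encounter_id[sel], readmission$encounter_id)
      elig <- readmission$eligible_index[k]
      re <- readmission$readmitted_30d[k]
      row$eligible_index_n <- sum(elig)
      row$readmission_n <- sum(re)
      row$readmission_pct <- if (sum(elig)) 100 * sum(re) / sum(elig) else
        NA_real_
      row$readmission_pct_all <- if (n) 100 * sum(re) / n else NA_real_
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- c(paste0("class", classes), "overall")
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Compare an outcome across classes
#'
#' Pearson chi-square either over the full class x outcome contingency table
#' (`comparison = "all_classes"`) or as a 2x2 one-vs-rest test for a named
#' class. Continuity correction is off by default; set `correct = TRUE` for
#' the Yates-corrected variant.
#'
#' @param events per-class event counts
#' @param totals per-class denominators
#' @param comparison `"all_classes"` or `"one_vs_rest"`
#' @param class class index for one-vs-rest
#' @param correct Yates continuity correction
#' @return list with `statistic`, `p_value`, `df`, and `warning` (message if
#'   any expected cell < 1, else `NULL`)
#' @export
compare_classes <- function(events, totals,
                            comparison = c("all_classes", "one_vs_rest"),
                            class = NULL, correct = FALSE) {
  comparison <- match.arg(comparison)
  if (comparison == "one_vs_rest") {
    if (is.null(class)) stop("one_vs_rest requires a class index")
    events <- c(events[class], sum(events[-class]))
    totals <- c(totals[class], sum(totals[-class]))
  }
  tab <- rbind(event = events, no_event = totals - events)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expected < 1)) "expected cell count below 1" else NULL
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter), warning = warn)
}

#' Plant per-class outcomes on a cohort of index encounters
#'
#' Outcomes-stage simulator: draws a discharge disposition for every
#' encounter from its class's disposition distribution, then plants one
#' future unplanned admission within 30 days for eligible index encounters
#' at the class readmission rate (plus occasional planned readmissions at
#' `planned_rate`, exercising the suppression rule).
#'
#' @param classes integer class per encounter
#' @param outcome_rates as [calibrated_outcome_rates()]
#' @param seed integer seed
#' @param study_days study window in days
#' @param planned_rate probability of planting a planned (suppressing)
#'   readmission instead of leaving the window untouched for non-readmitted
#'   encounters
#' @return list with `encounters` (index + planted rows), `diagnoses`
#'   (planned-readmission codes), `index_ids`, `study_end_day`
#' @export
simulate_class_outcomes <- function(classes,
                                    outcome_rates = calibrated_outcome_rates(),
                                    seed = 1L, study_days = 3000L,
                                    planned_rate = 0.01) {
  set.seed(seed)
  n <- length(classes)
  disp <- character(n)
  for (cl in sort(unique(classes))) {
    rows <- which(classes == cl)
    disp[rows] <- sample_cat(length(rows),
                             outcome_rates$disposition[cl, ],
                             colnames(outcome_rates$disposition))
  }
  admit_day <- runif(n, 0, study_days - 61)
  admit <- admit_day * 24
  dis <- admit + runif(n, 24, 96)
  enc <- data.frame(
    encounter_id = seq_len(n), patient_id = seq_len(n),
    admit_time = admit, discharge_time = dis, disposition = disp,
    stringsAsFactors = FALSE
  )
  dx <- data.frame(encounter_id = integer(), code = character(),
                   stringsAsFactors = FALSE)
  study_end_day <- as.integer(study_days)
  elig <- eligible_index(enc, dx, study_end_day)
  p_re <- outcome_rates$readmission[classes]
  u <- runif(n)
  plant_unplanned <- elig & u < p_re
  plant_planned <- elig & !plant_unplanned & runif(n) < planned_rate
  plant <- which(plant_unplanned | plant_planned)
  if (length(plant)) {
    offs <- sample(1:30, length(plant), replace = TRUE)
    new_admit <- (encounter_day(dis[plant]) + offs) * 24 + 6
    new_ids <- n + seq_along(plant)
    planted <- data.frame(
      encounter_id = new_ids, patient_id = plant,
      admit_time = new_admit, discharge_time = new_admit + 24,
      disposition = "home", stringsAsFactors = FALSE
    )
    enc <- rbind(enc, planted)
    pl_ids <- new_ids[plant_planned[plant]]
    if (length(pl_ids)) {
      dx <- data.frame(
        encounter_id = pl_ids,
        code = default_code_registry()$planned_readmission[1],
        stringsAsFactors = FALSE
      )
    }
  }
  list(encounters = enc, diagnoses = dx, index_ids = seq_len(n),
       study_end_day = study_end_day)
}
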