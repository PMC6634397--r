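# Rule engine for the operational definition of opioid misuse: any of
#   1. opiate-positive urine drug screen with polysubstance use (PCP or
#      cocaine; or a benzodiazepine / amphetamine not on the admission
#      medication list),
#   2. opiate-positive urine drug screen without an opioid on the admission
#      medication list,
#   3. a diagnosis code from the opioid-misuse code set;
# over eligible panels only (no opioid/benzodiazepine dispensed by the
# pharmacy at or before the order time), with transfers, patients under 18,
# and non-ED/inpatient services excluded.

#' Default code-set registry
#'
#' Maps code-set labels to synthetic code strings. Real deployments replace
#' these stand-ins with the institution's ICD-9/10 lists; the engine only
#' relies on tag membership.
#'
#' @return named list of character vectors
#' @export
default_code_registry <- function() {
  list(
    opioid_misuse_icd = c("OM001", "OM002", "OM003"),
    chronic_pain = c("CP001", "CP002"),
    alcohol_use_disorder = c("AU001"),
    psychoses = c("PS001"),
    depression = c("DE001"),
    liver = c("LI001"),
    drug_use = c("DU001"),
    planned_readmission = c("PL001", "PL002")
  )
}

#' Read a code-set registry from a YAML/JSON-style configuration file
#'
#' @param path JSON file mapping labels to arrays of code strings
#' @return named list of character vectors
#' @export
read_code_registry <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(reg, as.character)
}

registry_codes <- function(registry, tag) {
  if (!tag %in% names(registry)) {
    stop("unknown code-set tag '", tag, "' in registry")
  }
  codes <- registry[[tag]]
  if (!length(codes)) stop("code set '", tag, "' is empty")
  codes
}

included_services <- function() {
  c("ER", "medicine", "trauma", "surgery", "neurology", "other")
}

# min pharmacy dispense time of opioid/benzodiazepine per encounter; errors
# on dispense rows without a timestamp
min_blocking_dispense <- function(meds) {
  disp <- meds[meds$source == "inpatient_dispense" &
                 meds$drug_class %in% c("opioid", "benzodiazepine"), ,
               drop = FALSE]
  if (nrow(disp) && anyNA(disp$event_time)) {
    bad <- disp$encounter_id[is.na(disp$event_time)]
    stop("dispense events without event_time for encounter(s): ",
         paste(unique(bad), collapse = ", "))
  }
  disp
}

#' Urine-drug-screen eligibility
#'
#' A panel is eligible only if no opioid or benzodiazepine was dispensed by
#' the hospital pharmacy at or before the panel's order time (a tied
#' timestamp counts as dispensed-before). Medication sources other than
#' `inpatient_dispense` never affect eligibility.
#'
#' @param uds one UDS panel row (list/data.frame row with `order_time`)
#' @param meds medication events of the same encounter
#' @return logical flag
#' @export
uds_eligible <- function(uds, meds) {
  disp <- min_blocking_dispense(meds)
  !any(disp$event_time <= uds$order_time)
}

#' Misuse criterion 1: opiate-positive screen with polysubstance use
#'
#' True iff the panel is opiate positive together with PCP or cocaine
#' positivity, a benzodiazepine positive that is not on the admission
#' medication list, or an amphetamine positive that is not on the admission
#' medication list.
#'
#' @param uds one UDS panel row
#' @param meds medication events of the same encounter
#' @return logical flag
#' @export
criterion_polysubstance <- function(uds, meds) {
  adm <- meds$drug_class[meds$source == "admission_mar"]
  isTRUE(uds$opiate_pos) && (
    isTRUE(uds$pcp_pos) || isTRUE(uds$cocaine_pos) ||
      (isTRUE(uds$benzo_pos) && !"benzodiazepine" %in% adm) ||
      (isTRUE(uds$amphetamine_pos) && !"amphetamine" %in% adm)
  )
}

#' Misuse criterion 2: unexplained opiate-positive screen
#'
#' True iff the panel is opiate positive and no opioid appears on the
#' admission medication list (inpatient dispensing does not explain a
#' positive; it only affects panel eligibility).
#'
#' @inheritParams criterion_polysubstance
#' @return logical flag
#' @export
criterion_unexplained_opiate <- function(uds, meds) {
  adm <- meds$drug_class[meds$source == "admission_mar"]
  isTRUE(uds$opiate_pos) && !"opioid" %in% adm
}

#' Misuse criterion 3: opioid-related hospitalization code
#'
#' @param diagnoses diagnosis rows of the encounter (column `code`)
#' @param registry a code-set registry; must contain `opioid_misuse_icd`
#' @return logical flag
#' @export
criterion_icd <- function(diagnoses, registry = default_code_registry()) {
  any(diagnoses$code %in% registry_codes(registry, "opioid_misuse_icd"))
}

#' Evaluate the misuse definition for every encounter
#'
#' Vectorized rule engine over the full tables. Transfers, patients younger
#' than 18, and encounters outside the ED/inpatient services are excluded;
#' for the rest, criteria 1 and 2 are evaluated over eligible panels only
#' and criterion 3 over the encounter's diagnosis codes.
#'
#' @param encounters,uds,medications,diagnoses cohort tables as produced by
#'   [generate_cohort()]
#' @param registry code-set registry
#' @param services service values treated as ED/inpatient
#' @return data.frame with one row per encounter: `encounter_id`,
#'   `eligible_uds_ids` (semicolon-joined), `criterion1..3`, `is_misuse`,
#'   `exclusion_reason` (`NA` when included)
#' @export
evaluate_encounters <- function(encounters, uds, medications, diagnoses,
                                registry = default_code_registry(),
                                services = included_services()) {
  ids <- encounters$encounter_id
  for (tbl in list(uds = uds, medications = medications,
                   diagnoses = diagnoses)) {
    orphan <- setdiff(unique(tbl$encounter_id), ids)
    if (length(orphan)) {
      stop("rows reference unknown encounter id(s): ",
           paste(head(orphan, 10), collapse = ", "))
    }
  }
  n <- length(ids)
  pos <- function(eid) match(eid, ids)

  adm <- medications[medications$source == "admission_mar", , drop = FALSE]
  if (nrow(medications) &&
      !all(medications$source %in% c("admission_mar", "inpatient_dispense"))) {
    stop("medication source must be admission_mar or inpatient_dispense")
  }
  adm_opioid <- adm_benzo <- adm_amph <- logical(n)
  adm_opioid[pos(adm$encounter_id[adm$drug_class == "opioid"])] <- TRUE
  adm_benzo[pos(adm$encounter_id[adm$drug_class == "benzodiazepine"])] <- TRUE
  adm_amph[pos(adm$encounter_id[adm$drug_class == "amphetamine"])] <- TRUE

  disp <- min_blocking_dispense(medications)
  min_disp <- rep(Inf, n)
  if (nrow(disp)) {
    agg <- tapply(disp$event_time, disp$encounter_id, min)
    min_disp[pos(as.integer(names(agg)))] <- as.numeric(agg)
  }

  c1 <- c2 <- logical(n)
  elig_str <- character(n)
  if (nrow(uds)) {
    k <- pos(uds$encounter_id)
    eligible <- !(min_disp[k] <= uds$order_time)
    p1 <- uds$opiate_pos & (
      uds$pcp_pos | uds$cocaine_pos |
        (uds$benzo_pos & !adm_benzo[k]) |
        (uds$amphetamine_pos & !adm_amph[k]))
    p2 <- uds$opiate_pos & !adm_opioid[k]
    hit1 <- unique(k[eligible & p1])
    hit2 <- unique(k[eligible & p2])
    c1[hit1] <- TRUE
    c2[hit2] <- TRUE
    el <- which(eligible)
    if (length(el)) {
      grp <- split(uds$uds_id[el], k[el])
      elig_str[as.integer(names(grp))] <-
        vapply(grp, function(x) paste(x, collapse = ";"), character(1))
    }
  }

  c3 <- logical(n)
  om <- diagnoses[diagnoses$code %in%
                    registry_codes(registry, "opioid_misuse_icd"), ,
                  drop = FALSE]
  c3[unique(pos(om$encounter_id))] <- TRUE

  exclusion <- rep(NA_character_, n)
  exclusion[!encounters$service %in% services] <- "not_ed_or_inpatient"
  exclusion[encounters$age_years < 18] <- "pediatric"
  exclusion[encounters$is_transfer] <- "transfer"

  data.frame(
    encounter_id = ids,
    eligible_uds_ids = elig_str,
    criterion1 = c1, criterion2 = c2, criterion3 = c3,
    is_misuse = (c1 | c2 | c3) & is.na(exclusion),
    exclusion_reason = exclusion,
    stringsAsFactors = FALSE
  )
}

#' Evaluate the misuse definition for a single encounter
#'
#' Composes [uds_eligible()], [criterion_polysubstance()],
#' [criterion_unexplained_opiate()] and [criterion_icd()] for one encounter's
#' rows; criteria hold if any eligible panel satisfies them.
#'
#' @param encounter one encounter row
#' @param uds,meds,diagnoses rows of that encounter
#' @param registry code-set registry
#' @param services service values treated as ED/inpatient
#' @return one-row data.frame as in [evaluate_encounters()]
#' @export
evaluate_encounter <- function(encounter, uds, meds, diagnoses,
                               registry = default_code_registry(),
                               services = included_services()) {
  exclusion <- if (!encounter$service %in% services) "not_ed_or_inpatient"
    else if (encounter$age_years < 18) "pediatric"
    else if (isTRUE(encounter$is_transfer)) "transfer"
    else NA_character_
  elig <- logical(nrow(uds))
  c1p <- c2p <- logical(nrow(uds))
  for (i in seq_len(nrow(uds))) {
    panel <- uds[i, , drop = FALSE]
    elig[i] <- uds_eligible(panel, meds)
    c1p[i] <- criterion_polysubstance(panel, meds)
    c2p[i] <- criterion_unexplained_opiate(panel, meds)
  }
  c1 <- any(elig & c1p)
  c2 <- any(elig & c2p)
  c3 <- criterion_icd(diagnoses, registry)
  data.frame(
    encounter_id = encounter$encounter_id,
    eligible_uds_ids = paste(uds$uds_id[elig], collapse = ";"),
    criterion1 = c1, criterion2 = c2, criterion3 = c3,
    is_misuse = (c1 | c2 | c3) && is.na(exclusion),
    exclusion_reason = exclusion,
    stringsAsFactors = FALSE
  )
}

#' Build the analysis cohort from misuse evaluations
#'
#' @param evaluations output of [evaluate_encounters()]
#' @param encounters encounter table (for patient ids and admit times)
#' @param mode `"encounter_level"` keeps all misuse encounters;
#'   `"patient_level"` keeps, per patient, the misuse encounter with the
#'   latest admit time (the sensitivity analysis unit)
#' @return data.frame of misuse encounters with `patient_id` and `admit_time`
#' @export
build_cohort <- function(evaluations, encounters,
                         mode = c("encounter_level", "patient_level")) {
  mode <- match.arg(mode)
  keep <- evaluations[evaluations$is_misuse, , drop = FALSE]
  k <- match(keep$encounter_id, encounters$encounter_id)
  keep$patient_id <- encounters$patient_id[k]
  keep$admit_time <- encounters$admit_time[k]
  if (mode == "patient_level" && nrow(keep)) {
    ord <- order(keep$patient_id, -keep$admit_time, -keep$encounter_id)
    keep <- keep[ord, , drop = FALSE]
    keep <- keep[!duplicated(keep$patient_id), , drop = FALSE]
    keep <- keep[order(keep$encounter_id), , drop = FALSE]
  }
  rownames(keep) <- NULL
  keep
}

#' Derive the class-defining indicator matrix from the cohort tables
#'
#' Reconstructs the ten LCA items for the given encounters from the raw
#' tables: the five-level age band; six binary diagnosis-tag items; and the
#' three urine-drug-screen items evaluated over eligible panels (an untested
#' encounter scores "no" on each screen item, never missing).
#'
#' @param cohort_ids encounter ids to include (e.g. the misuse cohort)
#' @param encounters,uds,medications,diagnoses cohort tables
#' @param registry code-set registry
#' @return integer matrix (rows named by encounter id, columns per
#'   [default_indicator_spec()]); entries are level indices starting at 1
#' @export
build_indicator_matrix <- function(cohort_ids, encounters, uds, medications,
                                   diagnoses,
                                   registry = default_code_registry()) {
  spec <- default_indicator_spec()
  k <- match(cohort_ids, encounters$encounter_id)
  if (anyNA(k)) stop("cohort ids missing from encounter table")
  n <- length(cohort_ids)
  ind <- matrix(1L, n, nrow(spec),
                dimnames = list(as.character(cohort_ids), spec$name))
  bounds <- age_band_bounds()
  age <- encounters$age_years[k]
  band <- findInterval(age, c(0, 26, 36, 46, 55))
  ind[, "age_band"] <- pmin(pmax(band, 1L), 5L)

  tag_item <- c(liver = "liver", alcohol_use = "alcohol_use_disorder",
                psychoses = "psychoses", depression = "depression",
                chronic_pain = "chronic_pain",
                opioid_misuse_icd = "opioid_misuse_icd")
  for (item in names(tag_item)) {
    codes <- registry_codes(registry, tag_item[[item]])
    hit <- unique(diagnoses$encounter_id[diagnoses$code %in% codes])
    ind[cohort_ids %in% hit, item] <- 2L
  }

  # eligible-panel UDS items
  adm <- medications[medications$source == "admission_mar", , drop = FALSE]
  has_adm <- function(class) {
    unique(adm$encounter_id[adm$drug_class == class])
  }
  disp <- min_blocking_dispense(medications)
  min_disp <- tapply(disp$event_time, disp$encounter_id, min)
  md <- rep(Inf, nrow(uds))
  m <- match(as.character(uds$encounter_id), names(min_disp))
  md[!is.na(m)] <- as.numeric(min_disp)[m[!is.na(m)]]
  eligible <- !(md <= uds$order_time)
  ue <- uds[eligible, , drop = FALSE]
  op_unexpl <- unique(ue$encounter_id[ue$opiate_pos &
                                        !ue$encounter_id %in% has_adm("opioid")])
  cocaine <- unique(ue$encounter_id[ue$cocaine_pos])
  bz_unexpl <- unique(ue$encounter_id[
    ue$benzo_pos & !ue$encounter_id %in% has_adm("benzodiazepine")])
  ind[cohort_ids %in% op_unexpl, "uds_opiate_unexpl"] <- 2L
  ind[cohort_ids %in% cocaine, "uds_cocaine"] <- 2L
  ind[cohort_ids %in% bz_unexpl, "uds_benzo_unexpl"] <- 2L
  ind
}

#' Phenotyper recovery against the generator's ground truth
#'
#' @param evaluations output of [evaluate_encounters()]
#' @param ground_truth table from [ground_truth_table()]
#' @return list with `sensitivity`, `specificity`, and the 2x2 `table`
#' @export
phenotype_performance <- function(evaluations, ground_truth) {
  k <- match(evaluations$encounter_id, ground_truth$encounter_id)
  truth <- ground_truth$true_misuse[k]
  flag <- evaluations$is_misuse
  tab <- table(truth = factor(truth, c(FALSE, TRUE)),
               flagged = factor(flag, c(FALSE, TRUE)))
  list(
    sensitivity = tab["TRUE", "TRUE"] / sum(tab["TRUE", ]),
    specificity = tab["FALSE", "FALSE"] / sum(tab["FALSE", ]),
    table = tab
  )
}
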