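# Independent brute-force reference implementations used by the property
# suites. Deliberately written in the most literal style possible — no code
# shared with the package internals.

# ---- phenotyper truth-table oracle -----------------------------------------
# One encounter, at most one UDS panel, boolean features. Returns the misuse
# flag the written definition implies, derived straight from its prose.
oracle_misuse <- function(f) {
  if (f$transfer || f$age < 18 || !f$included_service) return(FALSE)
  c3 <- f$icd_misuse
  c1 <- c2 <- FALSE
  if (f$has_uds) {
    eligible <- !(f$disp_before)   # opioid/benzo dispensed at/before order
    if (eligible && f$opiate) {
      poly <- f$pcp || f$cocaine ||
        (f$benzo && !f$adm_benzo) || (f$amph && !f$adm_amph)
      c1 <- poly
      c2 <- !f$adm_opioid
    }
  }
  c1 || c2 || c3
}

# Build the single-encounter tables for a feature list and run the package's
# scalar evaluator on them.
pheno_case_tables <- function(f) {
  enc <- data.frame(
    encounter_id = 1L, patient_id = 1L,
    age_years = f$age, admit_time = 0, discharge_time = 100,
    first_vital_time = 1, naloxone_time = NA_real_,
    service = if (f$included_service) "medicine" else "outpatient_clinic",
    is_transfer = f$transfer, disposition = "home",
    elixhauser_score = 0, sex = "female", race = "white",
    insurance = "private", stringsAsFactors = FALSE
  )
  uds <- if (f$has_uds) {
    data.frame(uds_id = 1L, encounter_id = 1L, order_time = 10,
               opiate_pos = f$opiate, cocaine_pos = f$cocaine,
               pcp_pos = f$pcp, benzo_pos = f$benzo,
               amphetamine_pos = f$amph, stringsAsFactors = FALSE)
  } else {
    data.frame(uds_id = integer(), encounter_id = integer(),
               order_time = numeric(), opiate_pos = logical(),
               cocaine_pos = logical(), pcp_pos = logical(),
               benzo_pos = logical(), amphetamine_pos = logical(),
               stringsAsFactors = FALSE)
  }
  med <- data.frame(encounter_id = integer(), drug_class = character(),
                    source = character(), event_time = numeric(),
                    stringsAsFactors = FALSE)
  add_med <- function(med, cls, src, t) {
    rbind(med, data.frame(encounter_id = 1L, drug_class = cls, source = src,
                          event_time = t, stringsAsFactors = FALSE))
  }
  if (f$adm_opioid) med <- add_med(med, "opioid", "admission_mar", NA_real_)
  if (f$adm_benzo) med <- add_med(med, "benzodiazepine", "admission_mar",
                                  NA_real_)
  if (f$adm_amph) med <- add_med(med, "amphetamine", "admission_mar",
                                 NA_real_)
  if (f$disp_before) med <- add_med(med, "opioid", "inpatient_dispense", 5)
  if (f$disp_after) med <- add_med(med, "opioid", "inpatient_dispense", 50)
  dx <- if (f$icd_misuse) {
    data.frame(encounter_id = 1L, code = "OM001", stringsAsFactors = FALSE)
  } else {
    data.frame(encounter_id = integer(), code = character(),
               stringsAsFactors = FALSE)
  }
  list(encounters = enc, uds = uds, medications = med, diagnoses = dx)
}

# Enumerate the full micro-universe of phenotyper feature combinations.
pheno_universe <- function() {
  expand.grid(
    transfer = c(FALSE, TRUE),
    age = c(10L, 40L),
    included_service = c(FALSE, TRUE),
    has_uds = c(FALSE, TRUE),
    opiate = c(FALSE, TRUE),
    cocaine = c(FALSE, TRUE),
    pcp = c(FALSE, TRUE),
    benzo = c(FALSE, TRUE),
    amph = c(FALSE, TRUE),
    adm_opioid = c(FALSE, TRUE),
    adm_benzo = c(FALSE, TRUE),
    adm_amph = c(FALSE, TRUE),
    disp_before = c(FALSE, TRUE),
    disp_after = c(FALSE, TRUE),
    icd_misuse = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE
  )
}

# ---- readmission sequence oracle -------------------------------------------
# One patient, admissions given as (admit_day, length 1 day, planned flag,
# disposition, eligibility precomputed). Literal restatement of the rules:
# scan later admissions in order; same-day ignored; first in-window planned
# suppresses; at most one outcome.
oracle_readmit <- function(admit_days, planned, eligible) {
  n <- length(admit_days)
  flags <- logical(n)
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    disch_day <- admit_days[i]          # 1-day stays: discharge same day
    for (j in seq_len(n)) {
      if (j == i) next
      if (admit_days[j] <= admit_days[i]) next
      delta <- admit_days[j] - disch_day
      if (delta <= 0) next
      if (delta > 30) break
      if (planned[j]) break
      flags[i] <- TRUE
      break
    }
  }
  flags
}

# ---- LCA helpers ------------------------------------------------------------
# Log-likelihood of binary-coded data under explicit parameters, computed the
# slow literal way (per row, per class, per item).
oracle_loglik <- function(data, pi, rho) {
  ll <- 0
  for (i in seq_len(nrow(data))) {
    px <- 0
    for (c in seq_along(pi)) {
      p <- pi[c]
      for (j in seq_len(ncol(data))) p <- p * rho[[c]][[j]][data[i, j]]
      px <- px + p
    }
    ll <- ll + log(px)
  }
  ll
}
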