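# Synthetic EHR cohort generator. Emits the encounter / UDS / medication /
# diagnosis / census-tract tables plus a separate ground-truth table; the five
# data tables never carry the latent class.

sample_cat <- function(n, probs, labels = NULL) {
  idx <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  if (is.null(labels)) idx else labels[idx]
}

age_band_bounds <- function() {
  # adult bands used by the class-defining age item; the top two bands are
  # made disjoint at 55 so ages map back to a unique band
  cbind(lo = c(18, 26, 36, 46, 55), hi = c(25, 35, 45, 54, 90))
}

empty_cohort_tables <- function() {
  list(
    encounters = data.frame(
      encounter_id = integer(), patient_id = integer(), age_years = integer(),
      admit_time = numeric(), discharge_time = numeric(),
      first_vital_time = numeric(), naloxone_time = numeric(),
      service = character(), is_transfer = logical(),
      disposition = character(), elixhauser_score = numeric(),
      sex = character(), race = character(), insurance = character(),
      stringsAsFactors = FALSE
    ),
    uds = data.frame(
      uds_id = integer(), encounter_id = integer(), order_time = numeric(),
      opiate_pos = logical(), cocaine_pos = logical(), pcp_pos = logical(),
      benzo_pos = logical(), amphetamine_pos = logical(),
      stringsAsFactors = FALSE
    ),
    medications = data.frame(
      encounter_id = integer(), drug_class = character(),
      source = character(), event_time = numeric(), stringsAsFactors = FALSE
    ),
    diagnoses = data.frame(
      encounter_id = integer(), code = character(), stringsAsFactors = FALSE
    ),
    tracts = data.frame(
      patient_id = integer(), pct_poverty = numeric(),
      pct_employed = numeric(), pct_college = numeric(),
      pct_homeowner = numeric(), median_earnings = numeric(),
      stringsAsFactors = FALSE
    ),
    ground_truth = data.frame(
      encounter_id = integer(), true_misuse = logical(),
      true_class = integer(), stringsAsFactors = FALSE
    )
  )
}

#' Simulate class-defining indicators from a latent class model
#'
#' Draws a latent class for each row from the class prevalences and then each
#' categorical item from the class's item-response distribution. This is the
#' generative model that the latent class analysis is asked to recover.
#'
#' @param n rows to simulate
#' @param class_prevalences mixing proportions
#' @param item_response per-class list of per-item probability vectors
#' @param seed integer seed (set externally if `NULL`)
#' @return list with `indicators` (n x J integer matrix of level indices,
#'   columns named by item) and `true_class` (integer vector)
#' @export
simulate_indicators <- function(n,
                                class_prevalences = generating_class_prevalences(),
                                item_response = calibrated_item_response(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_simplex(class_prevalences, "class_prevalences")
  items <- names(item_response[[1]])
  true_class <- sample_cat(n, class_prevalences)
  ind <- matrix(1L, n, length(items), dimnames = list(NULL, items))
  for (cl in seq_along(class_prevalences)) {
    rows <- which(true_class == cl)
    if (!length(rows)) next
    for (j in seq_along(items)) {
      ind[rows, j] <- sample_cat(length(rows), item_response[[cl]][[items[j]]])
    }
  }
  list(indicators = ind, true_class = true_class)
}

#' Generate a synthetic EHR cohort
#'
#' Simulates `n_encounters` hospital encounters. A fraction
#' `misuse_prevalence` belongs to the opioid-misuse process: those encounters
#' draw a latent class, class-defining indicators, descriptors, and marker
#' tables constructed so that the operational misuse definition is satisfied.
#' Background encounters carry non-flagging noise (explained opiate
#' positives, cocaine-only positives, ineligible panels, chronic-pain codes)
#' plus the pediatric / transfer / outpatient records that the phenotyper
#' excludes.
#'
#' @param config a [cohort_config()]
#' @return list of class `ehr_cohort` with data.frames `encounters`, `uds`,
#'   `medications`, `diagnoses`, `tracts`, `ground_truth`, plus the `config`
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_encounters
  if (n == 0L) {
    out <- empty_cohort_tables()
    out$indicators <- matrix(
      integer(), 0, nrow(default_indicator_spec()),
      dimnames = list(NULL, default_indicator_spec()$name))
    out$config <- config
    class(out) <- "ehr_cohort"
    return(out)
  }
  desc <- class_descriptors()
  C <- length(config$class_prevalences)

  ## --- patients and timelines -------------------------------------------
  p_geo <- 1 / config$encounters_per_patient
  n_pat_guess <- max(10L, ceiling(n * p_geo * 1.6) + 10L)
  sizes <- 1L + rgeom(n_pat_guess, prob = p_geo)
  while (sum(sizes) < n) sizes <- c(sizes, 1L + rgeom(n_pat_guess, prob = p_geo))
  n_pat <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(n_pat)]
  patient_id <- rep(seq_len(n_pat), sizes)[seq_len(n)]
  occ <- sequence(sizes)[seq_len(n)]          # k-th encounter of its patient
  sizes_eff <- tabulate(patient_id, n_pat)

  # >= 120-day spacing between a patient's admissions keeps encounters
  # non-overlapping, leaves room for planted 30-day readmissions, and makes
  # the planted process the only source of 30-day readmissions
  span <- pmax(1, config$study_days - 35 - 120 * (sizes_eff - 1))
  base_day <- runif(n_pat) * span
  admit_day <- base_day[patient_id] + 120 * (occ - 1) + runif(n, 0, 20)
  admit_time <- admit_day * 24 + runif(n, 0, 24)
  los <- pmin(pmax(exp(rnorm(n, log(72), 0.7)), 2), 600)   # hours
  discharge_time <- admit_time + los
  first_vital_time <- admit_time + runif(n, 0, 2)

  ## --- misuse process ----------------------------------------------------
  true_misuse <- runif(n) < config$misuse_prevalence
  true_class <- rep(NA_integer_, n)
  items <- names(config$item_response[[1]])
  ind <- matrix(1L, n, length(items), dimnames = list(NULL, items))
  mis <- which(true_misuse)
  if (length(mis)) {
    sim <- simulate_indicators(length(mis), config$class_prevalences,
                               config$item_response, seed = NULL)
    true_class[mis] <- sim$true_class
    ind[mis, ] <- sim$indicators
  }
  cls <- true_class  # NA for background

  ## --- encounter attributes ---------------------------------------------
  bounds <- age_band_bounds()
  age_years <- integer(n)
  is_transfer <- logical(n)
  service <- character(n)
  sex <- character(n); race <- character(n); insurance <- character(n)
  elix <- numeric(n); disposition <- character(n)
  given_uds <- logical(n); naloxone <- logical(n)
  pcp_pos <- logical(n); amph_pos <- logical(n)

  bg <- which(!true_misuse)
  if (length(bg)) {
    nb <- length(bg)
    ped <- runif(nb) < config$pediatric_rate
    age_years[bg] <- ifelse(ped, sample(1:17, nb, TRUE), sample(18:90, nb, TRUE))
    is_transfer[bg] <- runif(nb) < config$transfer_rate
    outp <- runif(nb) < config$outpatient_rate
    service[bg] <- ifelse(
      outp, "outpatient_clinic",
      sample_cat(nb, colMeans(desc$service), colnames(desc$service)))
    sex[bg] <- sample_cat(nb, c(0.55, 0.45), c("male", "female"))
    race[bg] <- sample_cat(nb, colMeans(desc$race), colnames(desc$race))
    insurance[bg] <- sample_cat(nb, colMeans(desc$insurance),
                                colnames(desc$insurance))
    elix[bg] <- rnorm(nb, 1.5, 10)
    disposition[bg] <- sample_cat(
      nb, c(0.85, 0.02, 0.02, 0.01, 0.10),
      c("home", "psychiatric", "ama", "death", "other"))
    given_uds[bg] <- FALSE  # filled by background marker process below
    naloxone[bg] <- runif(nb) < 0.002
  }
  for (cl in seq_len(C)) {
    rows <- which(!is.na(cls) & cls == cl)
    if (!length(rows)) next
    nr <- length(rows)
    band <- ind[rows, "age_band"]
    age_years[rows] <- bounds[band, "lo"] +
      floor(runif(nr) * (bounds[band, "hi"] - bounds[band, "lo"] + 1))
    is_transfer[rows] <- FALSE
    service[rows] <- sample_cat(nr, desc$service[cl, ], colnames(desc$service))
    sex[rows] <- ifelse(runif(nr) < desc$male[cl], "male", "female")
    race[rows] <- sample_cat(nr, desc$race[cl, ], colnames(desc$race))
    insurance[rows] <- sample_cat(nr, desc$insurance[cl, ],
                                  colnames(desc$insurance))
    elix[rows] <- rnorm(nr, desc$elixhauser$mean[cl], desc$elixhauser$sd[cl])
    disposition[rows] <- sample_cat(
      nr, config$outcome_rates$disposition[cl, ],
      colnames(config$outcome_rates$disposition))
    given_uds[rows] <- runif(nr) < desc$given_uds[cl]
    naloxone[rows] <- runif(nr) < desc$naloxone[cl]
    pcp_pos[rows] <- runif(nr) < desc$pcp_pos[cl]
    amph_pos[rows] <- runif(nr) < desc$amph_pos[cl]
  }
  naloxone_time <- rep(NA_real_, n)
  nx <- which(naloxone)
  if (length(nx)) {
    naloxone_time[nx] <- first_vital_time[nx] +
      ifelse(runif(length(nx)) < 0.8, runif(length(nx), 0, 3),
             runif(length(nx), 3, 24))
  }

  ## --- misuse marker consistency ----------------------------------------
  # Indicator draws are kept exactly as sampled; encounters whose draws would
  # satisfy no criterion are made detectable through markers that are not
  # class-defining items (explained opiate positivity; amphetamine not on MAR).
  icd_yes   <- ind[, "opioid_misuse_icd"] == 2L & true_misuse
  op_unexpl <- ind[, "uds_opiate_unexpl"] == 2L & true_misuse
  coc_yes   <- ind[, "uds_cocaine"] == 2L & true_misuse
  bz_unexpl <- ind[, "uds_benzo_unexpl"] == 2L & true_misuse
  op_expl <- true_misuse & !icd_yes & !op_unexpl   # needs criterion 1 path
  rescue <- op_expl & !coc_yes & !bz_unexpl & !pcp_pos
  amph_pos <- amph_pos | rescue
  opiate_pos <- op_unexpl | op_expl
  benzo_pos <- bz_unexpl
  # encounters with any positive marker always have a panel
  given_uds <- given_uds | opiate_pos | coc_yes | benzo_pos | pcp_pos | amph_pos

  ## --- background marker noise ------------------------------------------
  bgr <- config$background
  bg_op_expl <- logical(n); bg_coc <- logical(n); bg_bz_expl <- logical(n)
  bg_op_inelig <- logical(n); bg_op_unexpl <- logical(n); bg_icd <- logical(n)
  if (length(bg)) {
    u <- matrix(runif(length(bg) * 6), ncol = 6)
    bg_op_expl[bg]   <- u[, 1] < bgr$explained_opiate
    bg_coc[bg]       <- u[, 2] < bgr$cocaine_only & !bg_op_expl[bg]
    bg_bz_expl[bg]   <- u[, 3] < bgr$explained_benzo
    bg_op_inelig[bg] <- u[, 4] < bgr$ineligible_opiate & !bg_op_expl[bg]
    bg_op_unexpl[bg] <- u[, 5] < bgr$unexplained_opiate & !bg_op_expl[bg] &
      !bg_op_inelig[bg]
    bg_icd[bg]       <- u[, 6] < bgr$misuse_icd
    bg_tested <- logical(n)
    bg_tested[bg] <- runif(length(bg)) < 0.08
    given_uds <- given_uds | bg_op_expl | bg_coc | bg_bz_expl | bg_op_inelig |
      bg_op_unexpl | bg_tested
    opiate_pos <- opiate_pos | bg_op_expl | bg_op_inelig | bg_op_unexpl
    benzo_pos <- benzo_pos | bg_bz_expl
  }
  coc_pos <- coc_yes | bg_coc

  ## --- UDS table ----------------------------------------------------------
  uds_rows <- which(given_uds)
  uds <- data.frame(
    uds_id = seq_along(uds_rows),
    encounter_id = uds_rows,
    order_time = admit_time[uds_rows] +
      runif(length(uds_rows)) * pmin(los[uds_rows] * 0.5, 12),
    opiate_pos = opiate_pos[uds_rows],
    cocaine_pos = coc_pos[uds_rows],
    pcp_pos = pcp_pos[uds_rows],
    benzo_pos = benzo_pos[uds_rows],
    amphetamine_pos = amph_pos[uds_rows],
    stringsAsFactors = FALSE
  )
  order_time <- rep(NA_real_, n)
  order_time[uds_rows] <- uds$order_time

  ## --- medication events --------------------------------------------------
  # admission medication list
  adm_opioid <- op_expl | bg_op_expl |
    (!opiate_pos & runif(n) < 0.05)               # incidental home opioids
  adm_benzo <- bg_bz_expl | (!benzo_pos & runif(n) < 0.03)
  adm_amph <- !amph_pos & runif(n) < 0.005
  # inpatient dispensing: opioids after the UDS order for a share of misuse
  # encounters (exercises the eligibility timing rule without breaking it),
  # and pre-order dispenses for the configured ineligible background panels
  disp_after <- true_misuse & given_uds & runif(n) < 0.30
  med_block <- function(ids, cls, src, times) {
    data.frame(encounter_id = ids, drug_class = rep(cls, length(ids)),
               source = rep(src, length(ids)), event_time = times,
               stringsAsFactors = FALSE)
  }
  med <- rbind(
    med_block(which(adm_opioid), "opioid", "admission_mar",
              rep(NA_real_, sum(adm_opioid))),
    med_block(which(adm_benzo), "benzodiazepine", "admission_mar",
              rep(NA_real_, sum(adm_benzo))),
    med_block(which(adm_amph), "amphetamine", "admission_mar",
              rep(NA_real_, sum(adm_amph))),
    med_block(which(disp_after), "opioid", "inpatient_dispense",
              order_time[which(disp_after)] + 1),
    med_block(which(bg_op_inelig), "opioid", "inpatient_dispense",
              pmax(order_time[which(bg_op_inelig)] - 1,
                   admit_time[which(bg_op_inelig)]))
  )
  med <- med[order(med$encounter_id), , drop = FALSE]
  rownames(med) <- NULL

  ## --- diagnoses ----------------------------------------------------------
  registry <- default_code_registry()
  dx_flag <- list(
    opioid_misuse_icd = icd_yes | bg_icd,
    chronic_pain = (ind[, "chronic_pain"] == 2L & true_misuse) |
      (!true_misuse & runif(n) < bgr$chronic_pain_icd),
    alcohol_use_disorder = (ind[, "alcohol_use"] == 2L & true_misuse) |
      (!true_misuse & runif(n) < 0.04),
    psychoses = (ind[, "psychoses"] == 2L & true_misuse) |
      (!true_misuse & runif(n) < 0.02),
    depression = (ind[, "depression"] == 2L & true_misuse) |
      (!true_misuse & runif(n) < 0.06),
    liver = (ind[, "liver"] == 2L & true_misuse) |
      (!true_misuse & runif(n) < 0.02),
    drug_use = true_misuse & runif(n) < desc$drug_use[ifelse(is.na(cls), 1, cls)]
  )
  dx <- do.call(rbind, lapply(names(dx_flag), function(tag) {
    rows <- which(dx_flag[[tag]])
    if (!length(rows)) return(NULL)
    data.frame(encounter_id = rows,
               code = sample(registry[[tag]], length(rows), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(dx)) dx <- empty_cohort_tables()$diagnoses
  dx <- dx[order(dx$encounter_id), , drop = FALSE]
  rownames(dx) <- NULL

  ## --- census tracts (one row per patient) -------------------------------
  # a patient's tract profile follows the class of their first misuse
  # encounter; background patients draw from the pooled profile
  pat_class <- rep(NA_integer_, n_pat)
  if (length(mis)) {
    first_mis <- mis[!duplicated(patient_id[mis])]
    pat_class[patient_id[first_mis]] <- cls[first_mis]
  }
  tp <- config$tract_params
  draw_tract <- function(par, cl_vec, lo = 0, hi = 100) {
    mu <- ifelse(is.na(cl_vec), mean(par$mean), par$mean[ifelse(is.na(cl_vec), 1, cl_vec)])
    sd <- ifelse(is.na(cl_vec), mean(par$sd), par$sd[ifelse(is.na(cl_vec), 1, cl_vec)])
    pmin(pmax(rnorm(n_pat, mu, sd), lo), hi)
  }
  tracts <- data.frame(
    patient_id = seq_len(n_pat),
    pct_poverty = draw_tract(tp$pct_poverty, pat_class),
    pct_employed = draw_tract(tp$pct_employed, pat_class),
    pct_college = draw_tract(tp$pct_college, pat_class),
    pct_homeowner = draw_tract(tp$pct_homeowner, pat_class),
    median_earnings = draw_tract(tp$median_earnings, pat_class, 0, Inf),
    stringsAsFactors = FALSE
  )

  encounters <- data.frame(
    encounter_id = seq_len(n), patient_id = patient_id,
    age_years = age_years, admit_time = admit_time,
    discharge_time = discharge_time, first_vital_time = first_vital_time,
    naloxone_time = naloxone_time, service = service,
    is_transfer = is_transfer, disposition = disposition,
    elixhauser_score = elix, sex = sex, race = race, insurance = insurance,
    stringsAsFactors = FALSE
  )
  ground_truth <- data.frame(
    encounter_id = seq_len(n), true_misuse = true_misuse,
    true_class = true_class, stringsAsFactors = FALSE
  )
  out <- list(encounters = encounters, uds = uds, medications = med,
              diagnoses = dx, tracts = tracts, ground_truth = ground_truth,
              indicators = ind[mis, , drop = FALSE], config = config)
  rownames(out$indicators) <- as.character(mis)
  class(out) <- "ehr_cohort"
  out
}

#' Ground-truth table of a synthetic cohort
#'
#' One row per encounter; `true_class` is present iff `true_misuse`. Kept
#' separate from the five data tables so recovery tests can join on
#' `encounter_id` without any leakage into the analysis inputs.
#'
#' @param cohort an `ehr_cohort`
#' @return data.frame with `encounter_id`, `true_misuse`, `true_class`
#' @export
ground_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  cohort$ground_truth
}

#' Generate concept-bag notes for the misuse encounters
#'
#' Each misuse encounter receives `notes_per_encounter` documents whose
#' concept tokens are drawn topic-first: a topic from the encounter class's
#' topic mixture, then a concept identifier from that topic's concept
#' distribution.
#'
#' @param cohort an `ehr_cohort` (or a list with `encounters` and
#'   `ground_truth`)
#' @param config a [cohort_config()]; defaults to the cohort's own
#' @param seed integer seed; defaults to the config seed's notes stage
#' @return data.frame of class `note_table` in long form: `note_id`,
#'   `encounter_id`, `concept`, `count`
#' @export
generate_notes <- function(cohort, config = cohort$config, seed = NULL) {
  gt <- ground_truth_table(cohort)
  set.seed(seed %||% derive_seed(config$seed, "notes"))
  mix <- config$topic_mixtures
  phi <- config$topic_word
  for (k in seq_len(nrow(phi))) check_simplex(phi[k, ], "topic_word")
  mis <- gt[gt$true_misuse, , drop = FALSE]
  if (!nrow(mis)) {
    out <- data.frame(note_id = integer(), encounter_id = integer(),
                      concept = character(), count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("note_table", "data.frame")
    return(out)
  }
  rng <- config$notes_per_encounter
  n_notes <- sample(rng[1]:rng[2], nrow(mis), replace = TRUE)
  note_enc <- rep(mis$encounter_id, n_notes)
  note_cls <- rep(mis$true_class, n_notes)
  note_id <- seq_along(note_enc)
  lens <- pmax(1L, rpois(length(note_id), config$note_length))
  tok_note <- rep(note_id, lens)
  tok_cls <- rep(note_cls, lens)
  z <- integer(length(tok_note))
  for (cl in sort(unique(note_cls))) {
    sel <- which(tok_cls == cl)
    z[sel] <- sample_cat(length(sel), mix[cl, ])
  }
  w <- integer(length(z))
  for (k in sort(unique(z))) {
    sel <- which(z == k)
    w[sel] <- sample_cat(length(sel), phi[k, ])
  }
  V <- ncol(phi)
  key <- (tok_note - 1L) * V + w
  cnt <- tabulate(key, nbins = length(note_id) * V)
  nz <- which(cnt > 0L)
  out <- data.frame(
    note_id = (nz - 1L) %/% V + 1L,
    encounter_id = note_enc[(nz - 1L) %/% V + 1L],
    concept = colnames(phi)[(nz - 1L) %% V + 1L],
    count = cnt[nz],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$note_id, out$concept), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("note_table", "data.frame")
  out
}
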