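#' Calibrated latent-class prevalences
#'
#' Mixing proportions of the four opioid-misuse subtypes used by the default
#' synthetic cohort: high hospital utilization with known opioid-related
#' conditions (36.5%), illicit use with low SES and psychoses (12.8%),
#' alcohol use disorders with complications (39.2%), and low hospital
#' utilization with incidental misuse (11.5%).
#'
#' @return Named numeric vector of length 4 summing to 1.
#' @export
calibrated_class_prevalences <- function() {
  p <- c(class1 = 0.365, class2 = 0.128, class3 = 0.392, class4 = 0.115)
  p / sum(p)
}

#' Generating class prevalences consistent with the calibrated shares
#'
#' The calibrated class shares in [calibrated_class_prevalences()] are
#' statistics of *assigned* classes (each encounter assigned to its maximum
#' posterior class), not mixture weights: modal assignment systematically
#' moves mass between overlapping classes, so a mixture generated directly
#' from those shares would not reproduce them after fitting and assignment.
#' This function inverts that mapping exactly. It enumerates all response
#' patterns of the indicator model, computes the population share of
#' patterns assigned to each class under candidate mixing weights, and
#' solves the fixed point where the assignment shares equal the target
#' shares. Deterministic given its arguments; no simulation involved.
#'
#' @param target desired assignment shares (a simplex vector)
#' @param item_response per-class item-response distributions as in
#'   [calibrated_item_response()]
#' @param max_iter,tol fixed-point iteration controls
#' @return mixing-proportion vector of the same length as `target`
#' @export
generating_class_prevalences <- function(
    target = calibrated_class_prevalences(),
    item_response = calibrated_item_response(),
    max_iter = 200L, tol = 1e-10) {
  C <- length(target)
  stopifnot(length(item_response) == C)
  levels <- vapply(item_response[[1]], length, integer(1))
  grid <- as.matrix(expand.grid(lapply(levels, seq_len)))
  lik <- vapply(seq_len(C), function(cl) {
    p <- rep(1, nrow(grid))
    for (j in seq_along(levels)) p <- p * item_response[[cl]][[j]][grid[, j]]
    p
  }, numeric(nrow(grid)))
  pi <- target
  for (it in seq_len(max_iter)) {
    w <- sweep(lik, 2, pi, "*")
    idx <- max.col(w, ties.method = "first")
    tot <- rowSums(w)
    S <- vapply(seq_len(C), function(r) sum(tot[idx == r]), numeric(1))
    if (max(abs(S - target)) < tol) break
    pi <- pi * (target / pmax(S, 1e-12))^0.5
    pi <- pi / sum(pi)
  }
  names(pi) <- names(target)
  pi
}

#' Calibrated item-response probabilities for the class-defining indicators
#'
#' Per-class categorical distributions for the ten LCA items: a five-level
#' age band (<=25, 26-35, 36-45, 46-55, >=55) plus nine binary items
#' (liver disease, alcohol use disorder, psychoses, depression, chronic
#' pain, opioid-misuse diagnosis code, and three urine-drug-screen items:
#' unexplained opiate positive, cocaine positive, unexplained benzodiazepine
#' positive). Values are the per-class column percentages of the published
#' characteristics of the four subtypes, taken as the generating model.
#'
#' @return List of length 4 (classes); each element a named list of per-item
#'   probability vectors summing to 1.
#' @export
calibrated_item_response <- function() {
  age <- rbind(
    c(10.3, 20.8, 18.1, 22.6, 28.1),
    c( 5.4, 20.4, 24.3, 38.3, 11.5),
    c( 2.4, 13.1, 20.8, 31.5, 32.2),
    c(10.9, 14.8, 13.2, 28.4, 32.6)
  ) / 100
  age <- sweep(age, 1, rowSums(age), "/")
  bin <- rbind(
    liver             = c(0.004, 0.070, 0.421, 0.122),
    alcohol_use       = c(0.004, 0.320, 0.840, 0.148),
    psychoses         = c(0.152, 0.251, 0.213, 0.223),
    depression        = c(0.219, 0.158, 0.279, 0.223),
    chronic_pain      = c(0.321, 0.283, 0.244, 0.391),
    opioid_misuse_icd = c(1.000, 0.791, 1.000, 0.259),
    uds_opiate_unexpl = c(0.078, 0.351, 0.037, 0.499),
    uds_cocaine       = c(0.000, 1.000, 0.036, 0.003),
    uds_benzo_unexpl  = c(0.000, 0.165, 0.009, 0.668)
  )
  lapply(1:4, function(cl) {
    out <- list(age_band = age[cl, ])
    for (item in rownames(bin)) {
      p <- unname(bin[item, cl])
      out[[item]] <- c(no = 1 - p, yes = p)
    }
    out
  })
}

#' Indicator specification for the default latent class model
#'
#' Ten items in eight named variable groups; the three urine-drug-screen
#' items share one group.
#'
#' @return data.frame with columns `name`, `levels`, `group`.
#' @export
default_indicator_spec <- function() {
  data.frame(
    name = c("age_band", "liver", "alcohol_use", "psychoses", "depression",
             "chronic_pain", "opioid_misuse_icd", "uds_opiate_unexpl",
             "uds_cocaine", "uds_benzo_unexpl"),
    levels = c(5L, rep(2L, 9L)),
    group = c("age", "liver disease", "alcohol use disorder", "psychoses",
              "depression", "chronic pain", "opioid-related hospitalization",
              rep("urine drug screen results", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Calibrated per-class clinical outcome rates
#'
#' 30-day unplanned readmission rates and discharge-disposition
#' distributions per latent class, matching the published outcome table.
#'
#' @return List with `readmission` (length-4 vector) and `disposition`
#'   (4 x 5 matrix over home/psychiatric/AMA/death/other, rows sum to 1).
#' @export
calibrated_outcome_rates <- function() {
  disp <- rbind(
    c(0.728, 0.030, 0.056, 0.020, 0.167),
    c(0.688, 0.066, 0.123, 0.019, 0.104),
    c(0.703, 0.063, 0.051, 0.030, 0.152),
    c(0.671, 0.055, 0.049, 0.039, 0.186)
  )
  colnames(disp) <- c("home", "psychiatric", "ama", "death", "other")
  rownames(disp) <- paste0("class", 1:4)
  disp <- sweep(disp, 1, rowSums(disp), "/")
  list(
    readmission = c(class1 = 0.139, class2 = 0.086,
                    class3 = 0.123, class4 = 0.083),
    disposition = disp
  )
}

#' Calibrated per-class topic mixtures
#'
#' Mean per-class probabilities of the twenty note topics (rows sum to 1
#' after renormalizing the printed percentages).
#'
#' @return 4 x 20 matrix; rows are classes, columns named by topic theme.
#' @export
calibrated_topic_mixtures <- function() {
  m <- rbind(
    c(15.2, 1.4, 10.1, 5.7, 6.8, 5.0, 6.7, 7.6, 5.8, 7.2,
      2.5, 4.0, 3.1, 0.9, 3.7, 3.7, 2.5, 3.0, 2.4, 2.8),
    c(22.5, 5.6, 5.7, 10.0, 4.5, 5.5, 4.6, 4.4, 4.1, 3.2,
      7.4, 5.0, 3.4, 1.5, 3.3, 1.5, 2.2, 2.5, 2.2, 1.1),
    c(7.9, 20.8, 8.0, 7.7, 5.7, 5.8, 5.0, 3.6, 5.1, 2.7,
      3.4, 2.4, 3.9, 6.5, 2.4, 1.6, 1.8, 1.4, 1.8, 1.8),
    c(11.3, 2.5, 7.4, 8.0, 7.5, 9.9, 6.1, 6.0, 3.9, 4.1,
      7.3, 6.6, 3.8, 2.6, 2.7, 1.7, 2.4, 2.5, 2.1, 1.7)
  ) / 100
  colnames(m) <- c(
    "polysubstance", "alcohol_withdrawal", "gi_pancreatitis", "mental_health",
    "physical_therapy", "neuro_seizures", "coronary_artery", "procedural_pain",
    "nursing_assessment", "cancer_pain", "trauma", "lower_extremity",
    "respiratory_failure", "liver_disease", "infection", "constipation",
    "non_coronary_heart", "appendage_injury", "renal", "vitamins"
  )
  rownames(m) <- paste0("class", 1:4)
  sweep(m, 1, rowSums(m), "/")
}

#' Default topic-concept distributions for the note generator
#'
#' Synthetic topic-word matrix: each of the K topics places its mass
#' uniformly on its own disjoint block of `block` concept identifiers, so
#' topics are separable by construction (a property the recovery tests
#' exploit; real clinical topics overlap far more).
#'
#' @param K topic count (default 20, matching the calibrated mixtures)
#' @param block concepts per topic
#' @return K x (K*block) matrix with rows summing to 1; columns named with
#'   synthetic concept identifiers `CUI0001`, ...
#' @export
default_topic_word <- function(K = 20L, block = 10L) {
  V <- K * block
  phi <- matrix(0, K, V, dimnames = list(NULL, sprintf("CUI%04d", seq_len(V))))
  for (k in seq_len(K)) {
    phi[k, ((k - 1L) * block + 1L):(k * block)] <- 1 / block
  }
  phi
}

# Non-LCA descriptor distributions per class (characteristics reporting and
# realism only; the phenotyper and LCA never read them as ground truth).
class_descriptors <- function() {
  list(
    male = c(0.508, 0.591, 0.736, 0.552),
    race = local({
      m <- rbind(
        c(0.418, 0.476, 0.085, 0.021),
        c(0.586, 0.308, 0.083, 0.023),
        c(0.324, 0.544, 0.099, 0.033),
        c(0.328, 0.536, 0.098, 0.038)
      )
      colnames(m) <- c("nh_black", "nh_white", "hispanic", "other")
      sweep(m, 1, rowSums(m), "/")
    }),
    insurance = local({
      m <- rbind(
        c(0.300, 0.188, 0.359, 0.153),
        c(0.113, 0.061, 0.503, 0.323),
        c(0.225, 0.180, 0.326, 0.268),
        c(0.256, 0.232, 0.329, 0.182)
      )
      colnames(m) <- c("medicare", "private", "medicaid", "uninsured")
      sweep(m, 1, rowSums(m), "/")
    }),
    service = local({
      m <- rbind(
        c(0.467, 0.269, 0.041, 0.069, 0.029, 0.126),
        c(0.600, 0.201, 0.140, 0.005, 0.019, 0.035),
        c(0.546, 0.280, 0.065, 0.047, 0.027, 0.036),
        c(0.552, 0.172, 0.185, 0.014, 0.027, 0.050)
      )
      colnames(m) <- c("ER", "medicine", "trauma", "surgery", "neurology",
                      "other")
      sweep(m, 1, rowSums(m), "/")
    }),
    elixhauser = list(mean = c(1.8, -0.7, 6.2, 5.9),
                      sd = c(12.3, 9.9, 13.0, 11.8)),
    given_uds = c(0.326, 1.000, 0.566, 1.000),
    naloxone = c(0.079, 0.099, 0.046, 0.105),
    pcp_pos = c(0.018, 0.035, 0.011, 0.021),
    amph_pos = c(0.011, 0.021, 0.008, 0.064),
    drug_use = c(0.820, 0.917, 0.570, 0.314),
    tract = list(
      pct_poverty = list(mean = c(13.0, 16.1, 12.1, 12.2),
                         sd = c(11.8, 12.3, 10.9, 10.7)),
      pct_employed = list(mean = c(38.4, 37.7, 37.9, 38.7),
                          sd = c(18.7, 16.7, 18.8, 18.2)),
      median_earnings = list(mean = c(47916, 42728, 47639, 49736),
                             sd = c(30177, 25078, 30980, 30934)),
      pct_college = list(mean = c(14.2, 12.3, 14.1, 14.9),
                         sd = c(9.6, 8.0, 9.5, 9.6)),
      pct_homeowner = list(mean = c(47.9, 46.1, 47.3, 49.2),
                           sd = c(24.0, 20.9, 24.5, 24.0))
    )
  )
}

#' Build a synthetic-cohort configuration
#'
#' Assembles and validates the configuration that drives [generate_cohort()].
#' Defaults emulate the source study's conditions: a 2.7% misuse prevalence
#' among 228,884 encounters, a four-class latent structure with the
#' calibrated prevalences and item-response probabilities, per-class topic
#' mixtures for the notes, and per-class outcome rates.
#'
#' @param n_encounters number of encounters in the universe
#' @param misuse_prevalence probability an encounter belongs to the misuse
#'   process (strictly between 0 and 1 unless 0/1 used for degenerate tests)
#' @param class_prevalences latent-class mixing proportions (sum to 1)
#' @param item_response per-class list of per-item probability vectors
#' @param outcome_rates list with `readmission` vector and `disposition`
#'   matrix, as [calibrated_outcome_rates()]
#' @param topic_mixtures per-class distribution over topics (rows sum to 1)
#' @param topic_word K x V topic-concept distributions (rows sum to 1)
#' @param notes_per_encounter integer range (min, max) of notes per misuse
#'   encounter
#' @param note_length mean concept tokens per note (Poisson, floored at 1)
#' @param tract_params per-class mean/SD lists for census-tract attributes
#' @param transfer_rate,pediatric_rate,outpatient_rate background rates of
#'   the records the phenotyper must exclude
#' @param encounters_per_patient mean encounters per patient (geometric)
#' @param background per-encounter background (non-misuse) marker rates; see
#'   Details
#' @param study_days length of the simulated study window in days
#' @param seed integer seed
#'
#' @details Background rates are non-flagging by default: opiate positives
#' are explained by an admission opioid, benzodiazepine positives by an
#' admission benzodiazepine, and cocaine positives occur without opiate
#' positivity, so none of them satisfies the misuse criteria. The two
#' flagging knobs (`unexplained_opiate`, `misuse_icd`) default to 0 and can
#' be raised to study the phenotyper's specificity.
#'
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_encounters = 228884L,
                          misuse_prevalence = 6224 / 228884,
                          class_prevalences = generating_class_prevalences(),
                          item_response = calibrated_item_response(),
                          outcome_rates = calibrated_outcome_rates(),
                          topic_mixtures = calibrated_topic_mixtures(),
                          topic_word = default_topic_word(),
                          notes_per_encounter = c(1L, 2L),
                          note_length = 80,
                          tract_params = class_descriptors()$tract,
                          transfer_rate = 0.03,
                          pediatric_rate = 0.02,
                          outpatient_rate = 0.01,
                          encounters_per_patient = 1.3,
                          background = list(),
                          study_days = 3900L,
                          seed = 1L) {
  bg_default <- list(
    explained_opiate = 0.010,    # opiate-positive UDS, opioid on admission MAR
    cocaine_only = 0.005,        # cocaine positive, opiate negative
    explained_benzo = 0.005,     # benzo positive, benzodiazepine on admission MAR
    ineligible_opiate = 0.005,   # opiate positive but opioid dispensed pre-order
    chronic_pain_icd = 0.100,
    unexplained_opiate = 0.000,  # flagging noise (criterion 2 false positives)
    misuse_icd = 0.000           # flagging noise (criterion 3 false positives)
  )
  background <- modifyList(bg_default, background)
  cfg <- structure(list(
    n_encounters = as.integer(n_encounters),
    misuse_prevalence = misuse_prevalence,
    class_prevalences = class_prevalences,
    item_response = item_response,
    outcome_rates = outcome_rates,
    topic_mixtures = topic_mixtures,
    topic_word = topic_word,
    notes_per_encounter = as.integer(notes_per_encounter),
    note_length = note_length,
    tract_params = tract_params,
    transfer_rate = transfer_rate,
    pediatric_rate = pediatric_rate,
    outpatient_rate = outpatient_rate,
    encounters_per_patient = encounters_per_patient,
    background = background,
    study_days = as.integer(study_days),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

check_simplex <- function(x, field, tol = 1e-9) {
  if (any(x < -tol)) stop("negative probability in field '", field, "'")
  if (abs(sum(x) - 1) > tol) {
    stop("field '", field, "' does not sum to 1 (sum = ", sum(x), ")")
  }
  invisible(TRUE)
}

#' Validate a cohort configuration
#'
#' @param cfg a `cohort_config`
#' @return the config, invisibly; stops with the offending field on error
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_encounters < 0) stop("field 'n_encounters' must be >= 0")
  if (cfg$misuse_prevalence < 0 || cfg$misuse_prevalence > 1) {
    stop("field 'misuse_prevalence' must lie in [0, 1]")
  }
  check_simplex(cfg$class_prevalences, "class_prevalences")
  for (cl in seq_along(cfg$item_response)) {
    for (item in names(cfg$item_response[[cl]])) {
      check_simplex(cfg$item_response[[cl]][[item]],
                    sprintf("item_response[class %d, %s]", cl, item))
    }
  }
  for (cl in seq_len(nrow(cfg$topic_mixtures))) {
    check_simplex(cfg$topic_mixtures[cl, ],
                  sprintf("topic_mixtures[class %d]", cl))
  }
  for (k in seq_len(nrow(cfg$topic_word))) {
    check_simplex(cfg$topic_word[k, ], sprintf("topic_word[topic %d]", k))
  }
  if (ncol(cfg$topic_mixtures) != nrow(cfg$topic_word)) {
    stop("field 'topic_word' row count must equal topic_mixtures column count")
  }
  check_simplex(rowSums(cfg$outcome_rates$disposition) /
                  nrow(cfg$outcome_rates$disposition), "disposition")
  rates <- c(cfg$outcome_rates$readmission, cfg$transfer_rate,
             cfg$pediatric_rate, cfg$outpatient_rate,
             unlist(cfg$background))
  if (any(rates < 0 | rates > 1)) stop("a rate lies outside [0, 1]")
  if (length(cfg$notes_per_encounter) != 2 ||
      cfg$notes_per_encounter[1] > cfg$notes_per_encounter[2] ||
      cfg$notes_per_encounter[1] < 0) {
    stop("field 'notes_per_encounter' must be a nondecreasing (min, max) pair")
  }
  invisible(cfg)
}
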