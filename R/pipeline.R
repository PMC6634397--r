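# End-to-end orchestration: generate -> phenotype -> LCA -> topics ->
# outcomes, with per-stage seeds derived from one global seed, CSV/JSONL
# outputs, and a run manifest.

#' Plant 30-day readmissions for a synthetic cohort
#'
#' Outcomes-stage generator step: for every misuse encounter that qualifies
#' as an eligible index admission, plants one future unplanned admission
#' within 30 days at its true class's readmission rate. Appends the planted
#' encounters (and ground-truth rows marking them non-misuse) to the cohort.
#'
#' @param cohort an `ehr_cohort`
#' @param seed integer seed (defaults to the outcomes stage of the config
#'   seed)
#' @return the cohort with augmented `encounters`/`ground_truth` and a
#'   `planted` data.frame (`index_id`, `planted_id`)
#' @export
plant_readmissions <- function(cohort,
                               seed = derive_seed(cohort$config$seed,
                                                  "outcomes")) {
  set.seed(seed)
  enc <- cohort$encounters
  gt <- cohort$ground_truth
  rates <- cohort$config$outcome_rates$readmission
  elig <- eligible_index(enc, cohort$diagnoses,
                         study_end_day = cohort$config$study_days)
  cand <- which(gt$true_misuse & elig)
  if (!length(cand)) {
    cohort$planted <- data.frame(index_id = integer(), planted_id = integer())
    return(cohort)
  }
  p <- rates[gt$true_class[cand]]
  hit <- cand[runif(length(cand)) < p]
  if (length(hit)) {
    offs <- sample(1:30, length(hit), replace = TRUE)
    new_admit <- (encounter_day(enc$discharge_time[hit]) + offs) * 24 + 8
    new_ids <- max(enc$encounter_id) + seq_along(hit)
    planted <- enc[hit, , drop = FALSE]
    planted$encounter_id <- new_ids
    planted$admit_time <- new_admit
    planted$discharge_time <- new_admit + 36
    planted$first_vital_time <- new_admit + 0.5
    planted$naloxone_time <- NA_real_
    planted$is_transfer <- FALSE
    planted$disposition <- "home"
    cohort$encounters <- rbind(enc, planted)
    cohort$ground_truth <- rbind(
      gt, data.frame(encounter_id = new_ids, true_misuse = FALSE,
                     true_class = NA_integer_))
    cohort$planted <- data.frame(index_id = enc$encounter_id[hit],
                                 planted_id = new_ids)
  } else {
    cohort$planted <- data.frame(index_id = integer(), planted_id = integer())
  }
  cohort
}

#' Write cohort tables to a directory
#'
#' One CSV per table, notes (if supplied) as JSON Lines (one object per
#' note: `note_id`, `encounter_id`, concept-to-count mapping), and a
#' manifest recording the seed and a config hash.
#'
#' @param cohort an `ehr_cohort`
#' @param dir output directory (created if needed)
#' @param notes optional `note_table`
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, notes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("encounters", "uds", "medications", "diagnoses", "tracts",
               "ground_truth")) {
    write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(notes)) write_notes_jsonl(notes, file.path(dir, "notes.jsonl"))
  cfg_path <- file.path(dir, "config.json")
  cfg <- cohort$config
  cfg$item_response <- lapply(cfg$item_response, function(x) lapply(x, unname))
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    seed = cohort$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_encounters = nrow(cohort$encounters),
    n_misuse_truth = sum(cohort$ground_truth$true_misuse),
    written = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Write notes as JSON Lines
#'
#' @param notes long-form `note_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(notes)) {
    by_note <- split(seq_len(nrow(notes)), notes$note_id)
    for (rows in by_note) {
      counts <- as.list(notes$count[rows])
      names(counts) <- notes$concept[rows]
      writeLines(jsonlite::toJSON(list(
        note_id = notes$note_id[rows[1]],
        encounter_id = notes$encounter_id[rows[1]],
        concepts = counts
      ), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a JSON Lines note file back into long form
#'
#' @param path file written by [write_notes_jsonl()]
#' @return a `note_table` data.frame
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    out <- data.frame(note_id = integer(), encounter_id = integer(),
                      concept = character(), count = integer())
    class(out) <- c("note_table", "data.frame")
    return(out)
  }
  parts <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(note_id = x$note_id, encounter_id = x$encounter_id,
               concept = names(x$concepts),
               count = as.integer(unlist(x$concepts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("note_table", "data.frame")
  out
}

#' Patient-characteristics report by class
#'
#' Per-class counts and percentages for demographics, insurance,
#' comorbidity code sets, urine-drug-screen positivity and naloxone, plus
#' mean (SD) census-tract attributes and the tract poverty categorization
#' (high >= 20.0%, middle 10.0-19.9%, low <= 9.9% of households below the
#' federal poverty level).
#'
#' @param cohort_ids encounter ids of the analysis cohort
#' @param class_labels integer class per cohort encounter
#' @param tables list with `encounters`, `uds`, `medications`, `diagnoses`,
#'   `tracts` (e.g. an `ehr_cohort`)
#' @param registry code-set registry
#' @return list with `categorical` (variable/level/class/n/pct) and
#'   `tract` (variable/class/mean/sd) data.frames
#' @export
characteristics_report <- function(cohort_ids, class_labels, tables,
                                   registry = default_code_registry()) {
  enc <- tables$encounters
  k <- match(cohort_ids, enc$encounter_id)
  if (anyNA(k)) stop("missing cohort encounter(s) in encounter table")
  classes <- sort(unique(class_labels))
  ind <- build_indicator_matrix(cohort_ids, enc, tables$uds,
                                tables$medications, tables$diagnoses,
                                registry)
  bands <- c("<=25", "26-35", "36-45", "46-54", ">=55")
  tr <- tables$tracts[match(enc$patient_id[k], tables$tracts$patient_id), ,
                      drop = FALSE]
  pov <- cut(tr$pct_poverty, c(-Inf, 10, 20, Inf), right = FALSE,
             labels = c("low", "middle", "high"))
  vars <- list(
    sex = enc$sex[k],
    age_band = bands[ind[, "age_band"]],
    race = enc$race[k],
    insurance = enc$insurance[k],
    service = enc$service[k],
    liver = c("no", "yes")[ind[, "liver"]],
    alcohol_use_disorder = c("no", "yes")[ind[, "alcohol_use"]],
    psychoses = c("no", "yes")[ind[, "psychoses"]],
    depression = c("no", "yes")[ind[, "depression"]],
    chronic_pain = c("no", "yes")[ind[, "chronic_pain"]],
    opioid_misuse_icd = c("no", "yes")[ind[, "opioid_misuse_icd"]],
    uds_opiate_unexpl = c("no", "yes")[ind[, "uds_opiate_unexpl"]],
    uds_cocaine = c("no", "yes")[ind[, "uds_cocaine"]],
    uds_benzo_unexpl = c("no", "yes")[ind[, "uds_benzo_unexpl"]],
    naloxone_early = c("no", "yes")[naloxone_early_flag(enc[k, ]) + 1L],
    tract_poverty = as.character(pov)
  )
  cat_rows <- list()
  for (v in names(vars)) {
    for (cl in classes) {
      sel <- class_labels == cl
      tab <- table(vars[[v]][sel], useNA = "no")
      if (!length(tab)) next
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        variable = v, level = names(tab), class = cl,
        n = as.integer(tab), pct = 100 * as.integer(tab) / sum(sel),
        stringsAsFactors = FALSE
      )
    }
  }
  tract_rows <- list()
  for (v in c("pct_poverty", "pct_employed", "pct_college", "pct_homeowner",
              "median_earnings")) {
    if (is.null(tr[[v]])) next
    for (cl in classes) {
      x <- tr[[v]][class_labels == cl]
      tract_rows[[length(tract_rows) + 1L]] <- data.frame(
        variable = v, class = cl, mean = mean(x, na.rm = TRUE),
        sd = sd(x, na.rm = TRUE), stringsAsFactors = FALSE
      )
    }
  }
  list(categorical = do.call(rbind, cat_rows),
       tract = do.call(rbind, tract_rows))
}

#' Fit-curve report over class counts
#'
#' @param selection result of [select_model()]
#' @return list with `table` (`C`, `loglik`, `k`, `bic`, `abic`, `caic`),
#'   `selected`, `rationale`
#' @export
fit_curve_report <- function(selection) {
  list(table = selection$table, selected = selection$selected,
       rationale = selection$rationale)
}

#' Run the full pipeline
#'
#' generate -> phenotype -> LCA -> topics -> outcomes, writing every stage's
#' outputs under `outdir` and returning the in-memory results plus a run
#' manifest. All randomness derives from `config$seed` via fixed per-stage
#' offsets, so identical config and seed give identical outputs.
#'
#' @param config a [cohort_config()]
#' @param outdir output directory
#' @param mode `"encounter_level"` or `"patient_level"` (sensitivity
#'   analysis: most recent misuse encounter per patient)
#' @param C_range class counts for the LCA sweep
#' @param n_starts EM restarts per class count
#' @param K topics to fit (`NULL` fits `ncol(config$topic_mixtures)`)
#' @param passes Gibbs sweeps
#' @param registry code-set registry
#' @return list of class `pipeline_result` (see Details in the vignette)
#' @export
run_pipeline <- function(config, outdir = tempfile("opioidlca_run_"),
                         mode = c("encounter_level", "patient_level"),
                         C_range = 1:8, n_starts = 20L, K = NULL,
                         passes = 250L,
                         registry = default_code_registry()) {
  mode <- match.arg(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  cohort <- generate_cohort(config)
  cohort <- plant_readmissions(cohort)
  notes <- generate_notes(cohort)
  write_cohort(cohort, file.path(outdir, "cohort"), notes = notes)

  ev <- evaluate_encounters(cohort$encounters, cohort$uds,
                            cohort$medications, cohort$diagnoses, registry)
  analysis <- build_cohort(ev, cohort$encounters, mode = mode)
  write.csv(analysis, file.path(outdir, "misuse_cohort.csv"),
            row.names = FALSE)

  ind <- build_indicator_matrix(analysis$encounter_id, cohort$encounters,
                                cohort$uds, cohort$medications,
                                cohort$diagnoses, registry)
  sel <- select_model(ind, C_range = C_range, n_starts = n_starts,
                      seed = derive_seed(seed, "lca"))
  fit <- sel$fits[[as.character(sel$selected)]]
  post <- posterior_matrix(ind, fit$params)
  labels <- assign_classes(post)
  names(labels) <- analysis$encounter_id
  write.csv(cbind(C = sel$table$C, sel$table[-1]),
            file.path(outdir, "lca_fit_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pi = fit$params$pi,
         rho = lapply(fit$params$rho, function(x) lapply(x, unname))),
    file.path(outdir, "lca_params.json"), digits = NA)
  write.csv(data.frame(encounter_id = analysis$encounter_id, post),
            file.path(outdir, "lca_posterior.csv"), row.names = FALSE)
  write.csv(data.frame(encounter_id = analysis$encounter_id, class = labels),
            file.path(outdir, "lca_assignments.csv"), row.names = FALSE)

  topics_out <- NULL
  if (nrow(notes)) {
    vocab <- build_vocabulary(notes)
    corpus <- build_corpus(notes, vocab)
    Kfit <- K %||% ncol(config$topic_mixtures)
    model <- fit_topic_model(corpus, Kfit, passes = passes,
                             seed = derive_seed(seed, "topics"))
    etd <- encounter_topic_distribution(model, corpus)
    enc_with_topics <- intersect(rownames(etd),
                                 as.character(analysis$encounter_id))
    ctm <- class_topic_matrix(etd[enc_with_topics, , drop = FALSE],
                              labels[enc_with_topics])
    write.csv(vocab, file.path(outdir, "vocabulary.csv"), row.names = FALSE)
    write.csv(ctm, file.path(outdir, "class_topic_matrix.csv"))
    topics_out <- list(vocabulary = vocab, model = model,
                       encounter_topics = etd, class_topic = ctm)
  }

  flags <- flag_unplanned_readmission_30d(cohort$encounters,
                                          cohort$diagnoses,
                                          study_end_day = config$study_days,
                                          registry = registry)
  cohort_enc <- cohort$encounters[
    match(analysis$encounter_id, cohort$encounters$encounter_id), ,
    drop = FALSE]
  otab <- outcome_table(cohort_enc, labels,
                        flags[match(analysis$encounter_id,
                                    flags$encounter_id), ])
  write.csv(otab, file.path(outdir, "outcome_table.csv"))
  chars <- characteristics_report(analysis$encounter_id, labels, cohort,
                                  registry)
  write.csv(chars$categorical, file.path(outdir, "characteristics.csv"),
            row.names = FALSE)

  manifest <- list(
    seed = seed,
    mode = mode,
    stage_rows = list(
      encounters = nrow(cohort$encounters), notes = nrow(notes),
      misuse_cohort = nrow(analysis), planted = nrow(cohort$planted)
    ),
    selected_C = sel$selected,
    package_version = as.character(utils::packageVersion("opioidlca"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE)

  structure(list(
    cohort = cohort, notes = notes, evaluations = ev, analysis = analysis,
    indicators = ind, selection = sel, fit = fit, posterior = post,
    labels = labels, topics = topics_out, readmission = flags,
    outcome_table = otab, characteristics = chars, manifest = manifest,
    outdir = outdir
  ), class = "pipeline_result")
}
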