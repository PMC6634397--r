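# Topic modelling over concept-identifier bags: document-frequency
# vocabulary filter, collapsed-Gibbs LDA, UMass coherence, and the
# class x topic matrix used to validate latent classes against the notes.

#' Document-frequency vocabulary filter
#'
#' Keeps a concept iff its document frequency df (fraction of notes
#' containing it at least once) satisfies `min_df < df < max_df` — both
#' bounds strict, so concepts at exactly 10% or 70% are removed.
#'
#' @param notes long-form note table (`note_id`, `concept`, `count`)
#' @param min_df,max_df strict document-frequency bounds
#' @return data.frame of class `concept_vocabulary`: `concept`, `df`,
#'   `kept`, ordered by concept
#' @export
build_vocabulary <- function(notes, min_df = 0.10, max_df = 0.70) {
  if (!nrow(notes)) stop("empty note table")
  n_notes <- length(unique(notes$note_id))
  present <- notes[notes$count > 0, c("note_id", "concept")]
  df <- table(unique(present)$concept) / n_notes
  out <- data.frame(concept = names(df), df = as.numeric(df),
                    stringsAsFactors = FALSE)
  out$kept <- out$df > min_df & out$df < max_df
  out <- out[order(out$concept), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concept_vocabulary", "data.frame")
  out
}

#' Build a concept corpus over a vocabulary
#'
#' @param notes long-form note table (`note_id`, `encounter_id`, `concept`,
#'   `count`)
#' @param vocabulary a [build_vocabulary()] result (only `kept` concepts are
#'   used) or a character vector of concepts
#' @return list of class `concept_corpus` with `dtm` (notes x V count
#'   matrix), `note_id`, `encounter_id`, `vocabulary`, and `empty` (notes
#'   with no retained concept)
#' @export
build_corpus <- function(notes, vocabulary = build_vocabulary(notes)) {
  vocab <- if (is.character(vocabulary)) sort(vocabulary) else
    vocabulary$concept[vocabulary$kept]
  if (!length(vocab)) stop("vocabulary is empty after filtering")
  note_ids <- sort(unique(notes$note_id))
  d <- match(notes$note_id, note_ids)
  v <- match(notes$concept, vocab)
  keep <- !is.na(v) & notes$count > 0
  dtm <- matrix(0L, length(note_ids), length(vocab),
                dimnames = list(note_ids, vocab))
  dtm[cbind(d[keep], v[keep])] <- as.integer(notes$count[keep])
  enc <- notes$encounter_id[match(note_ids, notes$note_id)]
  structure(list(
    dtm = dtm, note_id = note_ids, encounter_id = enc, vocabulary = vocab,
    empty = note_ids[rowSums(dtm) == 0]
  ), class = "concept_corpus")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Point estimates of the topic-concept distributions `phi` and per-note
#' topic distributions `theta` are taken from the smoothed counts after
#' `passes` full sweeps of the collapsed Gibbs chain.
#'
#' @param corpus a [build_corpus()] result
#' @param K topic count (>= 1)
#' @param passes full Gibbs sweeps over the corpus
#' @param alpha,beta symmetric Dirichlet smoothing for theta and phi
#' @param seed integer seed (the chain is deterministic given it)
#' @return list of class `topic_model`: `K`, `phi` (K x V), `theta`
#'   (notes x K), `alpha`, `beta`, `passes`, `seed`
#' @export
fit_topic_model <- function(corpus, K, passes = 250L, alpha = 0.1,
                            beta = 0.01, seed = 1L) {
  stopifnot(inherits(corpus, "concept_corpus"), K >= 1)
  D <- nrow(corpus$dtm)
  V <- ncol(corpus$dtm)
  if (K > D) warning("more topics (", K, ") than documents (", D, ")")
  nz <- which(corpus$dtm > 0L, arr.ind = TRUE)
  cnt <- corpus$dtm[nz]
  doc <- rep.int(nz[, 1], cnt) - 1L
  word <- rep.int(nz[, 2], cnt) - 1L
  set.seed(seed)
  res <- lda_gibbs_cpp(doc, word, D, V, as.integer(K), as.integer(passes),
                       alpha, beta)
  phi <- res$phi
  colnames(phi) <- corpus$vocabulary
  theta <- res$theta
  rownames(theta) <- rownames(corpus$dtm)
  structure(list(K = as.integer(K), phi = phi, theta = theta, alpha = alpha,
                 beta = beta, passes = as.integer(passes), seed = seed),
            class = "topic_model")
}

#' UMass topic coherence
#'
#' For each topic's `top_n` highest-probability concepts (ordered by phi),
#' sums `log((D(w_m, w_l) + 1) / D(w_l))` over ordered pairs `l < m`, where
#' `D` counts documents containing the concept(s). Higher (closer to 0) is
#' more coherent.
#'
#' @param model a [fit_topic_model()] result
#' @param corpus the corpus the model was fitted on
#' @param top_n concepts per topic (clipped to the vocabulary size with a
#'   warning)
#' @return list with `per_topic` (numeric vector) and `mean`
#' @export
topic_coherence <- function(model, corpus, top_n = 10L) {
  V <- ncol(corpus$dtm)
  if (top_n > V) {
    warning("top_n exceeds vocabulary size; clipping to ", V)
    top_n <- V
  }
  B <- corpus$dtm > 0L
  per_topic <- vapply(seq_len(model$K), function(k) {
    if (top_n < 2L) return(0)
    top <- order(model$phi[k, ], decreasing = TRUE)[seq_len(top_n)]
    co <- crossprod(B[, top, drop = FALSE])   # pairwise doc co-occurrence
    dw <- diag(co)
    s <- 0
    for (m in 2:top_n) {
      for (l in seq_len(m - 1)) {
        if (dw[l] > 0) s <- s + log((co[m, l] + 1) / dw[l])
      }
    }
    s
  }, numeric(1))
  list(per_topic = per_topic, mean = mean(per_topic))
}

#' Select the topic count by mean coherence
#'
#' Fits an LDA model for every K in `K_range` and returns the K maximizing
#' mean UMass coherence (ties break toward the smallest K), together with
#' the full coherence curve.
#'
#' @param corpus a [build_corpus()] result
#' @param K_range topic counts to try
#' @param passes,alpha,beta,seed passed to [fit_topic_model()] (each K uses
#'   a seed derived from `seed`)
#' @param top_n concepts per topic for coherence
#' @return list with `curve` (data.frame `K`, `coherence`), `selected`,
#'   `models`
#' @export
select_topic_count <- function(corpus, K_range, passes = 250L, alpha = 0.1,
                               beta = 0.01, seed = 1L, top_n = 10L) {
  if (!length(K_range)) stop("K_range must be non-empty")
  K_range <- sort(unique(as.integer(K_range)))
  models <- lapply(K_range, function(K) {
    fit_topic_model(corpus, K, passes = passes, alpha = alpha, beta = beta,
                    seed = seed + K)
  })
  coh <- vapply(models, function(m) topic_coherence(m, corpus,
                                                    top_n = top_n)$mean,
                numeric(1))
  curve <- data.frame(K = K_range, coherence = coh)
  list(curve = curve, selected = K_range[which.max(coh)], models = models)
}

#' Aggregate note-level topic distributions to encounters
#'
#' @param model a [fit_topic_model()] result
#' @param corpus the corpus the model was fitted on (provides the
#'   note-to-encounter links)
#' @param weight `"note"` (unweighted mean over a encounter's notes, the
#'   default) or `"token"` (concept-count weighted)
#' @return matrix (encounters x K) with rows summing to 1, rownames the
#'   encounter ids; encounters whose notes all emptied under the vocabulary
#'   filter receive a uniform distribution with a warning
#' @export
encounter_topic_distribution <- function(model, corpus,
                                         weight = c("note", "token")) {
  weight <- match.arg(weight)
  w <- if (weight == "note") rep(1, nrow(model$theta)) else
    rowSums(corpus$dtm)
  enc <- corpus$encounter_id
  encs <- sort(unique(enc))
  out <- matrix(0, length(encs), model$K,
                dimnames = list(encs, colnames(model$theta)))
  for (i in seq_along(encs)) {
    rows <- which(enc == encs[i])
    wi <- w[rows]
    if (sum(wi) == 0) wi <- rep(1, length(rows))
    out[i, ] <- colSums(model$theta[rows, , drop = FALSE] * wi) / sum(wi)
  }
  tok <- tapply(rowSums(corpus$dtm), enc, sum)
  if (any(tok == 0)) {
    warning("encounter(s) with no retained concepts: uniform distribution ",
            "assigned: ", paste(names(tok)[tok == 0], collapse = ", "))
    out[tok[as.character(encs)] == 0, ] <- 1 / model$K
  }
  out
}

#' Class x topic probability matrix
#'
#' Entry (c, k) is the mean probability of topic k over the encounters
#' assigned to class c — the face-validity summary comparing note content
#' across latent classes.
#'
#' @param encounter_topics matrix from [encounter_topic_distribution()]
#' @param class_labels integer labels named by (or aligned with) the
#'   encounter ids of `encounter_topics`
#' @return C x K matrix; rows sum to 1; empty classes are dropped with a
#'   warning
#' @export
class_topic_matrix <- function(encounter_topics, class_labels) {
  if (!is.null(names(class_labels))) {
    class_labels <- class_labels[rownames(encounter_topics)]
  }
  if (length(class_labels) != nrow(encounter_topics) || anyNA(class_labels)) {
    stop("class labels do not cover the encounters with topics")
  }
  classes <- sort(unique(class_labels))
  out <- t(vapply(classes, function(c) {
    colMeans(encounter_topics[class_labels == c, , drop = FALSE])
  }, numeric(ncol(encounter_topics))))
  rownames(out) <- paste0("class", classes)
  all_classes <- seq_len(max(classes))
  missing <- setdiff(all_classes, classes)
  if (length(missing)) {
    warning("empty class(es) omitted: ", paste(missing, collapse = ", "))
  }
  out
}

#' Match fitted topics to reference topics
#'
#' Greedy pairing minimizing L1 distance between topic-concept rows (columns
#' are aligned by name when both matrices have column names). Returns `perm`
#' such that fitted topic `perm[r]` corresponds to reference topic `r`.
#'
#' @param fitted,reference K x V topic-concept matrices
#' @return integer permutation of `1:K`
#' @export
match_topics <- function(fitted, reference) {
  if (nrow(fitted) != nrow(reference)) stop("topic counts differ")
  if (!is.null(colnames(fitted)) && !is.null(colnames(reference))) {
    common <- intersect(colnames(reference), colnames(fitted))
    ref <- matrix(0, nrow(reference), ncol(fitted),
                  dimnames = list(NULL, colnames(fitted)))
    ref[, common] <- reference[, common]
    reference <- ref
  }
  K <- nrow(fitted)
  d <- matrix(0, K, K)
  for (f in seq_len(K)) for (r in seq_len(K)) {
    d[f, r] <- sum(abs(fitted[f, ] - reference[r, ]))
  }
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    perm[idx[2]] <- idx[1]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  perm
}
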