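# Latent class analysis for multivariate categorical indicators.
#
# Model: P(y) = sum_c pi_c prod_j rho[c, j, y_j], with class prevalences pi
# and item-response probabilities rho. Estimated by EM over unique response
# patterns (collapsing identical rows makes each iteration O(#patterns)
# instead of O(n)); model selection over a range of class counts with
# BIC / aBIC / cAIC.

#' Construct latent class parameters
#'
#' @param pi class prevalences (sum to 1)
#' @param rho list (length C) of lists (length J) of per-item level
#'   probability vectors, each summing to 1
#' @return object of class `lca_params`
#' @export
lca_params <- function(pi, rho) {
  stopifnot(length(pi) == length(rho))
  check_simplex(pi, "pi")
  J <- length(rho[[1]])
  for (c in seq_along(rho)) {
    if (length(rho[[c]]) != J) stop("inconsistent item count across classes")
    for (j in seq_len(J)) {
      check_simplex(rho[[c]][[j]], sprintf("rho[class %d, item %d]", c, j))
    }
  }
  structure(list(C = length(pi), pi = as.numeric(pi), rho = rho),
            class = "lca_params")
}

# item level counts implied by parameters
param_levels <- function(params) vapply(params$rho[[1]], length, integer(1))

# number of free parameters: (C-1) + C * sum(R_j - 1)
lca_n_params <- function(C, levels) (C - 1L) + C * sum(levels - 1L)

check_indicator_matrix <- function(data, levels) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (ncol(data) != length(levels)) {
    stop("indicator matrix has ", ncol(data), " items; parameters imply ",
         length(levels))
  }
  if (anyNA(data)) stop("missing indicator values are not supported")
  for (j in seq_along(levels)) {
    if (any(data[, j] < 1L | data[, j] > levels[j])) {
      stop("item ", j, " has entries outside 1..", levels[j])
    }
  }
  data
}

# one-hot expansion of an indicator matrix: n x sum(R_j) 0/1 matrix
one_hot <- function(data, levels) {
  n <- nrow(data)
  off <- c(0L, cumsum(levels))[seq_along(levels)]
  Y <- matrix(0, n, sum(levels))
  for (j in seq_along(levels)) {
    Y[cbind(seq_len(n), off[j] + data[, j])] <- 1
  }
  Y
}

# collapse identical response patterns; returns unique matrix + weights
collapse_patterns <- function(data, levels) {
  radix <- cumprod(c(1, levels[-length(levels)]))
  key <- as.vector((data - 1L) %*% radix)
  ord <- order(key)
  uk <- unique(key[ord])
  idx <- match(uk, key)
  list(unique = data[idx, , drop = FALSE],
       weight = as.numeric(tabulate(match(key, uk), length(uk))),
       map = match(key, uk))
}

# flatten rho into C x sum(R_j) matrix of log probabilities; exact zeros are
# clamped to a large finite negative value so that the one-hot matrix product
# never produces 0 * -Inf = NaN for unobserved levels
log_rho_matrix <- function(params, levels) {
  C <- params$C
  lr <- matrix(0, C, sum(levels))
  for (c in seq_len(C)) lr[c, ] <- log(unlist(params$rho[[c]]))
  pmax(lr, log(1e-300))
}

# n x C matrix of log pi_c + sum_j log rho_{c,j,y_ij}
class_loglik_matrix <- function(Y, params, levels) {
  lr <- log_rho_matrix(params, levels)
  sweep(Y %*% t(lr), 2, log(params$pi), "+")
}

#' Log likelihood of an indicator matrix under latent class parameters
#'
#' @param data n x J integer matrix of level indices
#' @param params an [lca_params()]
#' @return scalar log likelihood
#' @export
lca_loglik <- function(data, params) {
  levels <- param_levels(params)
  data <- check_indicator_matrix(data, levels)
  if (!nrow(data)) return(0)
  Y <- one_hot(data, levels)
  sum(row_logsumexp(class_loglik_matrix(Y, params, levels)))
}

# one EM run from given starting parameters on collapsed patterns;
# returns params, loglik trace, convergence flag
run_em <- function(Yu, w, levels, pi0, lrho0, max_iter, tol, floor = 1e-6) {
  n <- sum(w)
  C <- length(pi0)
  off <- c(0L, cumsum(levels))
  lpi <- log(pi0)
  lrho <- lrho0   # C x S log rho
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lm <- sweep(Yu %*% t(lrho), 2, lpi, "+")
    lse <- row_logsumexp(lm)
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    post <- exp(lm - lse)            # u x C
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    wpost <- post * w
    pi <- pmax(colSums(wpost) / n, 1e-12)
    pi <- pi / sum(pi)
    counts <- crossprod(Yu, wpost)   # S x C
    rho <- matrix(0, C, nrow(counts))
    for (j in seq_along(levels)) {
      cols <- (off[j] + 1L):off[j + 1L]
      blk <- t(counts[cols, , drop = FALSE])            # C x R_j
      blk <- blk / rowSums(blk)
      blk <- pmax(blk, floor)                           # smoothing floor
      rho[, cols] <- blk / rowSums(blk)
    }
    lpi <- log(pi)
    lrho <- log(rho)
  }
  list(pi = exp(lpi), lrho = lrho, loglik = ll, trace = trace,
       converged = converged, n_iter = iter)
}

lrho_to_params <- function(pi, lrho, levels, item_names = NULL) {
  off <- c(0L, cumsum(levels))
  rho <- lapply(seq_along(pi), function(c) {
    out <- lapply(seq_along(levels), function(j) {
      v <- exp(lrho[c, (off[j] + 1L):off[j + 1L]])
      v / sum(v)
    })
    names(out) <- item_names
    out
  })
  lca_params(pi / sum(pi), rho)
}

#' Fit a latent class model by EM with random restarts
#'
#' Runs `n_starts` EM runs from random initializations (item-response rows
#' from flat Dirichlet draws, uniform prevalences) and keeps the best
#' log-likelihood solution. Item-response probabilities are floored at
#' `1e-6` in the M-step to avoid log(0) on degenerate cells.
#'
#' @param data n x J integer matrix of level indices (columns may be named)
#' @param C number of latent classes (>= 1)
#' @param n_starts random restarts
#' @param max_iter maximum EM iterations per start
#' @param tol relative log-likelihood change declaring convergence
#' @param seed integer seed (restarts are drawn sequentially from it)
#' @param levels per-item level counts; inferred from the data by default
#' @return object of class `lca_fit`: `params`, `loglik`, `k`, `bic`,
#'   `abic`, `caic`, `n`, `n_iter`, `n_starts`, `converged`, `seed`,
#'   `loglik_trace` (best start)
#' @export
lca_em <- function(data, C, n_starts = 20L, max_iter = 5000L, tol = 1e-8,
                   seed = 1L, levels = NULL) {
  data <- as.matrix(data)
  if (!nrow(data)) stop("empty indicator matrix")
  if (C < 1L) stop("C must be >= 1")
  if (nrow(data) < C) stop("need at least C rows")
  if (is.null(levels)) levels <- pmax(apply(data, 2, max), 2L)
  data <- check_indicator_matrix(data, levels)
  set.seed(seed)
  cp <- collapse_patterns(data, levels)
  Yu <- one_hot(cp$unique, levels)
  S <- sum(levels)
  best <- NULL
  for (s in seq_len(n_starts)) {
    pi0 <- rep(1 / C, C)
    g <- matrix(rgamma(C * S, 1), C, S)
    off <- c(0L, cumsum(levels))
    for (j in seq_along(levels)) {
      cols <- (off[j] + 1L):off[j + 1L]
      g[, cols] <- g[, cols, drop = FALSE] /
        rowSums(g[, cols, drop = FALSE])
    }
    run <- run_em(Yu, cp$weight, levels, pi0, log(g), max_iter, tol)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  params <- lrho_to_params(best$pi, best$lrho, levels, colnames(data))
  n <- nrow(data)
  k <- lca_n_params(C, levels)
  fs <- fit_statistics(list(loglik = best$loglik, k = k), n)
  structure(list(
    params = params, loglik = best$loglik, k = k,
    bic = fs[["bic"]], abic = fs[["abic"]], caic = fs[["caic"]],
    n = n, n_iter = best$n_iter, n_starts = n_starts,
    converged = best$converged, seed = seed,
    loglik_trace = best$trace
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf(
    "Latent class model: C = %d, n = %d\n  loglik %.3f  (k = %d)\n  BIC %.2f  aBIC %.2f  cAIC %.2f\n  converged: %s after %d iterations (best of %d starts)\n",
    x$params$C, x$n, x$loglik, x$k, x$bic, x$abic, x$caic,
    x$converged, x$n_iter, x$n_starts))
  invisible(x)
}

#' Penalized-likelihood fit statistics
#'
#' BIC = -2l + k ln n; aBIC = -2l + k ln((n + 2) / 24);
#' cAIC = -2l + k (ln n + 1).
#'
#' @param fit list with `loglik` and `k` (e.g. an `lca_fit`)
#' @param n sample size (> 0)
#' @return named numeric vector `bic`, `abic`, `caic`
#' @export
fit_statistics <- function(fit, n) {
  if (n <= 0) stop("n must be positive")
  d <- -2 * fit$loglik
  c(bic = d + fit$k * log(n),
    abic = d + fit$k * log((n + 2) / 24),
    caic = d + fit$k * (log(n) + 1))
}

#' Fit latent class models over a range of class counts and select one
#'
#' Fits every C in `C_range` and selects the class count by the BIC elbow
#' rule: the smallest C whose relative BIC improvement over the previous
#' class count falls below `threshold` — the first class count at which fit
#' gains have diminished below a meaningful margin. If every step clears the
#' threshold, the BIC-minimizing C is returned. `method = "min"` selects the
#' BIC minimum directly. The full fit
#' table is always returned for human review; automatic selection is a proxy
#' for the published practice of weighing fit indices together with class
#' prevalence and interpretability.
#'
#' @param data indicator matrix
#' @param C_range class counts to fit (default 1:8)
#' @param n_starts,max_iter,tol,seed passed to [lca_em()]; each C uses a
#'   seed derived from `seed` so fits are independent but reproducible
#' @param method `"elbow"` (default) or `"min"`
#' @param threshold relative BIC-improvement threshold for the elbow rule
#' @return list with `fits` (per-C `lca_fit`s), `table` (one row per C),
#'   `selected` (chosen class count), `rationale` (string)
#' @export
select_model <- function(data, C_range = 1:8, n_starts = 20L,
                         max_iter = 5000L, tol = 1e-8, seed = 1L,
                         method = c("elbow", "min"), threshold = 0.01) {
  method <- match.arg(method)
  if (!length(C_range)) stop("C_range must be non-empty")
  C_range <- sort(unique(as.integer(C_range)))
  fits <- lapply(C_range, function(C) {
    tryCatch(
      lca_em(data, C, n_starts = n_starts, max_iter = max_iter, tol = tol,
             seed = seed + C),
      error = function(e) stop("lca_em failed for C = ", C, ": ",
                               conditionMessage(e))
    )
  })
  names(fits) <- C_range
  tab <- data.frame(
    C = C_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    abic = vapply(fits, `[[`, numeric(1), "abic"),
    caic = vapply(fits, `[[`, numeric(1), "caic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  rownames(tab) <- NULL
  if (method == "min" || length(C_range) == 1L) {
    selected <- C_range[which.min(tab$bic)]
    rationale <- sprintf("BIC minimum at C = %d", selected)
  } else {
    # rel_gain[i] is the relative BIC improvement achieved when moving from
    # C_range[i] to C_range[i + 1]
    rel_gain <- (tab$bic[-nrow(tab)] - tab$bic[-1]) /
      abs(tab$bic[-nrow(tab)])
    stop_at <- which(rel_gain < threshold)
    if (length(stop_at)) {
      i <- stop_at[1]
      if (rel_gain[i] > 0) {
        # a real but sub-threshold improvement: accept the class it bought
        selected <- C_range[i + 1L]
        rationale <- sprintf(
          paste0("elbow rule: relative BIC improvement from C = %d to ",
                 "C = %d (%.2f%%) is the first below %.1f%%"),
          C_range[i], selected, 100 * rel_gain[i], 100 * threshold)
      } else {
        # BIC worsened outright: stop before the extra class
        selected <- C_range[i]
        rationale <- sprintf(
          "elbow rule: BIC stops improving after C = %d", selected)
      }
    } else {
      selected <- C_range[which.min(tab$bic)]
      rationale <- sprintf(
        "all BIC improvements exceed %.1f%%; BIC minimum at C = %d",
        100 * threshold, selected)
    }
  }
  list(fits = fits, table = tab, selected = selected, rationale = rationale)
}

#' Posterior class-membership probabilities
#'
#' Bayes rule per row: `pi_c prod_j rho[c,j,y_ij]` normalized over classes.
#'
#' @param data indicator matrix
#' @param params an [lca_params()]
#' @return n x C matrix with rows summing to 1
#' @export
posterior_matrix <- function(data, params) {
  levels <- param_levels(params)
  data <- check_indicator_matrix(data, levels)
  Y <- one_hot(data, levels)
  lm <- class_loglik_matrix(Y, params, levels)
  post <- exp(lm - row_logsumexp(lm))
  rownames(post) <- rownames(data)
  post
}

#' Modal class assignment
#'
#' Argmax of the posterior per row; ties break toward the lowest class index.
#'
#' @param posterior n x C posterior matrix
#' @return integer class labels
#' @export
assign_classes <- function(posterior) {
  max.col(posterior, ties.method = "first")
}

#' Class-separation diagnostics
#'
#' Mean (and SD) of the assigned-class posterior probability within each
#' assigned class; values near 1 indicate unambiguous assignment.
#'
#' @param posterior n x C posterior matrix
#' @param labels assignments from [assign_classes()]
#' @return data.frame with `class`, `n`, `mean_posterior`, `sd_posterior`
#' @export
class_separation <- function(posterior, labels = assign_classes(posterior)) {
  C <- ncol(posterior)
  p_assigned <- posterior[cbind(seq_len(nrow(posterior)), labels)]
  out <- data.frame(class = seq_len(C), n = tabulate(labels, C),
                    mean_posterior = NA_real_, sd_posterior = NA_real_)
  for (c in seq_len(C)) {
    v <- p_assigned[labels == c]
    if (!length(v)) {
      warning("class ", c, " has no assigned rows")
      next
    }
    out$mean_posterior[c] <- mean(v)
    out$sd_posterior[c] <- if (length(v) > 1) sd(v) else 0
  }
  out
}

#' Match fitted classes to reference classes
#'
#' Resolves label switching: finds the permutation `perm` (by exhaustive
#' search, C <= 8) minimizing the total L1 distance between item-response
#' profiles, such that fitted class `perm[r]` corresponds to reference class
#' `r`.
#'
#' @param fitted,reference [lca_params()] with identical class counts and
#'   item structure
#' @return integer permutation of `1:C`
#' @export
match_classes <- function(fitted, reference) {
  if (fitted$C != reference$C) stop("class counts differ")
  C <- fitted$C
  if (C > 8L) stop("exhaustive matching supported for C <= 8")
  lf <- param_levels(fitted); lr <- param_levels(reference)
  if (!identical(lf, lr)) stop("item structures differ")
  fm <- exp(log_rho_matrix(fitted, lf))
  rm <- exp(log_rho_matrix(reference, lr))
  d <- matrix(0, C, C)  # d[f, r] = L1 distance fitted f vs reference r
  for (f in seq_len(C)) for (r in seq_len(C)) {
    d[f, r] <- sum(abs(fm[f, ] - rm[r, ]))
  }
  perms <- all_permutations(C)
  costs <- vapply(perms, function(p) sum(d[cbind(p, seq_len(C))]), numeric(1))
  perms[[which.min(costs)]]
}

all_permutations <- function(C) {
  if (C == 1L) return(list(1L))
  sub <- all_permutations(C - 1L)
  out <- vector("list", C * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(C)) {
    i <- i + 1L
    out[[i]] <- append(p, C, after = pos - 1L)
  }
  out
}

#' Reorder fitted parameters to a reference labelling
#'
#' @param params an [lca_params()]
#' @param perm permutation from [match_classes()]
#' @return relabelled [lca_params()]
#' @export
apply_class_permutation <- function(params, perm) {
  lca_params(params$pi[perm], params$rho[perm])
}
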