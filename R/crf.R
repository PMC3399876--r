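#' Linear-chain CRF over sentence-subset states
#'
#' The sentences-in-states (SIS) CRF generalizes the SIS HMM: a state is any
#' subset of the article's sentences of size at most `D_max` (default 2),
#' with the empty set as the non-linked state, so a single path can link one
#' figure with several sentences. Transition affinities are log-linear in
#' eight shared features of the (source, destination) subset pair, which
#' lets information learned on frequent transitions generalize to rare ones
#' (e.g. a common penalty for transitions that induce crossed edges).
#' Emission affinities reuse the Gaussian score calibration of the HMM.
#' The FIS variant swaps the roles of sentences and figures; in that case
#' the "figure degree" one-hot below reads on sentence degree.
#'
#' @name crf
NULL

crf_feature_names <- c("FigureDegree0", "FigureDegree1", "FigureDegree2",
                       "FigureDegree3plus", "EdgesCrossed", "PreviousFigure",
                       "PreviousSentence", "PrevSentAndFig")

#' Enumerate CRF states
#'
#' All subsets of `{1..n_s}` with at most `D_max` elements, ordered by size
#' then lexicographically; the first state is the empty (non-linked) set.
#'
#' @param n_s Number of sentences.
#' @param D_max Maximum state cardinality.
#' @return List of sorted integer vectors.
#' @export
enumerate_states <- function(n_s, D_max) {
  if (n_s < 1 || D_max < 1) stop("need n_s >= 1 and D_max >= 1")
  out <- list(integer(0))
  for (d in seq_len(min(D_max, n_s))) {
    cmb <- utils::combn(n_s, d)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

#' Transition features between two subset states
#'
#' For source state `A` (sentences of the previous figure) and destination
#' `A'` (sentences of the current figure):
#' a one-hot of `|A'|` (degree 0/1/2/3+); `EdgesCrossed`, the number of
#' pairs `i in A', i' in A` with `i' > i` (each induces a crossed edge in the
#' order diagram); `PreviousFigure = |A intersect A'|`;
#' `PreviousSentence`, the number of `i in A'` with `i - 1 in A'` (counted on
#' the destination only, to avoid double counting across consecutive
#' transitions); and `PrevSentAndFig`, the number of `i in A'` with
#' `i - 1 in A`.
#'
#' @param A,A_dest Integer vectors (source and destination subsets).
#' @return Named numeric vector of length 8.
#' @export
transition_features <- function(A, A_dest) {
  d <- length(A_dest)
  f <- stats::setNames(numeric(8), crf_feature_names)
  f[min(d, 3L) + 1L] <- 1
  if (length(A) && d)
    f["EdgesCrossed"] <- sum(outer(A_dest, A, function(i, ip) ip > i))
  f["PreviousFigure"] <- length(intersect(A, A_dest))
  if (d) f["PreviousSentence"] <- sum((A_dest - 1L) %in% A_dest)
  if (length(A) && d) f["PrevSentAndFig"] <- sum((A_dest - 1L) %in% A)
  f
}

#' Start-state features
#'
#' The features associated with beginning a path in state `A'`: evaluated as
#' [transition_features()] with an empty source, so all source-dependent
#' features are 0.
#'
#' @param A_dest Destination subset.
#' @return Named numeric vector of length 8.
#' @export
start_features <- function(A_dest) transition_features(integer(0), A_dest)

# Feature array for a state list: F[s, s', m] plus start matrix [s, m].
# Cached per (n, D_max) since every article of the same size shares it.
crf_cache <- new.env(parent = emptyenv())

crf_structure <- function(n, D_max) {
  key <- paste0(n, "_", D_max)
  if (!is.null(crf_cache[[key]])) return(crf_cache[[key]])
  states <- enumerate_states(n, D_max)
  S <- length(states)
  Fmat <- array(0, c(S, S, 8))
  for (a in seq_len(S)) for (b in seq_len(S))
    Fmat[a, b, ] <- transition_features(states[[a]], states[[b]])
  startF <- t(vapply(states, start_features, numeric(8)))
  inc <- matrix(FALSE, n, S)
  for (s in seq_len(S)) inc[states[[s]], s] <- TRUE
  res <- list(states = states, F = Fmat,
              Fflat = matrix(Fmat, S * S, 8), startF = startF, inc = inc)
  crf_cache[[key]] <- res
  res
}

state_index <- function(states, A) {
  key <- vapply(states, function(s) paste(s, collapse = ","), "")
  match(paste(sort(A), collapse = ","), key)
}

#' Emission affinities over subset states
#'
#' `E[s, k]` is proportional to the joint Gaussian density of the step's
#' score column when exactly the sentences in `A(s)` are linked, normalized
#' over states within each step. For `n_s = 1` this reduces to the HMM
#' emission probabilities over states `{}` and `{1}`.
#'
#' @param Z `n x n_steps` score matrix.
#' @param emission An `fl_emission` (see [fit_emission()]).
#' @param states State list from [enumerate_states()].
#' @param log Return log probabilities?
#' @return `length(states) x n_steps` matrix; columns sum to 1 (on the
#'   probability scale).
#' @export
emission_affinities <- function(Z, emission, states, log = FALSE) {
  Z <- unclass(Z)
  lr <- apply(Z, 2, emission_log_ratio, em = emission)
  lr <- matrix(lr, nrow = nrow(Z))
  logE <- vapply(seq_len(ncol(Z)), function(k)
    vapply(states, function(A) sum(lr[A, k]), 1), numeric(length(states)))
  logE <- matrix(logE, nrow = length(states))
  logE <- sweep(logE, 2, apply(logE, 2, log_sum_exp))
  if (log) logE else exp(logE)
}

#' Unnormalized path probability
#'
#' Product of the start-state affinity `exp(w . f_start)`, the emission
#' affinities of each step, and the transition affinities
#' `exp(w . f(s_{k-1} -> s_k))`; computed in log space.
#'
#' @param path List of subsets (length = number of steps).
#' @param w Weight vector (length 8).
#' @param E Emission affinity matrix over `states` (columns = steps).
#' @param states State list.
#' @return Positive scalar.
#' @export
path_unnormalized_prob <- function(path, w, E, states) {
  idx <- vapply(path, function(A) state_index(states, A), 1L)
  if (anyNA(idx)) stop("path contains a subset that is not a state")
  lp <- sum(w * start_features(path[[1]])) + log(E[idx[1], 1])
  for (k in seq_along(path)[-1])
    lp <- lp + sum(w * transition_features(path[[k - 1]], path[[k]])) +
      log(E[idx[k], k])
  exp(lp)
}

# log-space forward/backward. Returns log alpha, log beta, logZ.
crf_forward_backward <- function(logT, log_start_aff, logE) {
  S <- nrow(logE); K <- ncol(logE)
  la <- matrix(-Inf, S, K)
  la[, 1] <- log_start_aff + logE[, 1]
  lse_cols <- function(M) {
    mx <- apply(M, 2, max)
    ifelse(is.finite(mx), mx + log(colSums(exp(sweep(M, 2, mx)))), mx)
  }
  if (K > 1) for (k in 2:K)
    la[, k] <- lse_cols(logT + la[, k - 1]) + logE[, k]
  lb <- matrix(0, S, K)
  if (K > 1) for (k in (K - 1):1) {
    M <- t(logT) + (lb[, k + 1] + logE[, k + 1])  # M[s', s] broadcast over rows
    lb[, k] <- lse_cols(M)
  }
  list(log_alpha = la, log_beta = lb, logZ = log_sum_exp(la[, K]),
       logZ_backward = log_sum_exp(log_start_aff + logE[, 1] + lb[, 1]))
}

# Per-article sufficient statistics for training / prediction.
crf_article_data <- function(article, S, variant, D_max, emission) {
  L <- article$linkage
  Z <- unclass(S)
  if (variant == "fis") { L <- if (!is.null(L)) t(L); Z <- t(Z) }
  n <- nrow(Z)
  str <- crf_structure(n, D_max)
  logE <- emission_affinities(Z, emission, str$states, log = TRUE)
  path_idx <- NULL; truncated <- 0L
  if (!is.null(L)) {
    path <- lapply(seq_len(ncol(L)), function(k) which(L[, k] == 1))
    path <- lapply(path, function(A) {
      if (length(A) > D_max) { truncated <<- truncated + 1L; A[seq_len(D_max)] }
      else A
    })
    path_idx <- vapply(path, function(A) state_index(str$states, A), 1L)
  }
  list(structure = str, logE = logE, path_idx = path_idx,
       n_steps = ncol(Z), truncated = truncated)
}

# Observed feature counts of a training path.
crf_observed <- function(ad) {
  str <- ad$structure; idx <- ad$path_idx
  f <- str$startF[idx[1], ]
  for (k in seq_along(idx)[-1]) f <- f + str$F[idx[k - 1], idx[k], ]
  f
}

# Expected feature counts and log-likelihood pieces for one article.
crf_expected <- function(ad, w) {
  str <- ad$structure
  logT <- matrix(str$Fflat %*% w, nrow(str$startF))
  lsa <- as.vector(str$startF %*% w)
  fb <- crf_forward_backward(logT, lsa, ad$logE)
  K <- ad$n_steps
  lgamma1 <- fb$log_alpha[, 1] + fb$log_beta[, 1] - fb$logZ
  g1 <- exp(lgamma1)
  exp_f <- as.vector(g1 %*% str$startF)
  if (K > 1) {
    M <- matrix(0, nrow(logT), ncol(logT))
    for (k in 2:K) {
      lxi <- outer(fb$log_alpha[, k - 1], ad$logE[, k] + fb$log_beta[, k], "+") +
        logT - fb$logZ
      M <- M + exp(lxi)
    }
    exp_f <- exp_f + as.vector(t(str$Fflat) %*% as.vector(M))
  }
  list(expected = exp_f, logZ = fb$logZ, fb = fb)
}

#' Train the CRF by gradient ascent
#'
#' Maximizes the regularized conditional log-likelihood of the training
#' paths (each figure's gold sentence set, truncated to its `D_max`
#' lowest-indexed sentences when larger) over the transition weight vector.
#' The gradient is observed minus expected feature counts from
#' forward-backward, minus `l2 * w`. Optimized with batch L-BFGS on the
#' analytic gradient; deterministic (zero initialization, no
#' stochasticity).
#'
#' @param corpus Training corpus with gold linkage.
#' @param scores List of per-article score matrices (same order).
#' @param variant `"sis"` or `"fis"`.
#' @param D_max Maximum sentences per state (default 2).
#' @param emission Optional pre-fitted `fl_emission`; fitted from `scores`
#'   and the gold labels when omitted.
#' @param l2 L2 regularization strength (default 1e-2; 0 disables).
#' @param max_iter,tol Stopping rule: gradient infinity-norm below `tol` or
#'   `max_iter` iterations.
#' @return Object of class `fl_crf`: `w` (named weights), `D_max`,
#'   `variant`, `emission`, convergence info.
#' @export
train_crf <- function(corpus, scores, variant = c("sis", "fis"), D_max = 2L,
                      emission = NULL, l2 = 1e-2, max_iter = 200L,
                      tol = 1e-4) {
  variant <- match.arg(variant)
  if (is.null(emission)) {
    z <- unlist(lapply(scores, as.vector))
    y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
    emission <- fit_emission(z, y)
  }
  ads <- mapply(crf_article_data, corpus, scores,
                MoreArgs = list(variant = variant, D_max = D_max,
                                emission = emission),
                SIMPLIFY = FALSE)
  n_trunc <- sum(vapply(ads, function(a) a$truncated, 1L))
  if (n_trunc > 0)
    message(n_trunc, " training figure(s) linked > D_max sentences; truncated")
  obs <- Reduce(`+`, lapply(ads, crf_observed))
  emis_ll <- sum(vapply(ads, function(ad)
    sum(ad$logE[cbind(ad$path_idx, seq_len(ad$n_steps))]), 1))

  obj_grad <- function(w) {
    ex <- lapply(ads, crf_expected, w = w)
    logZ <- sum(vapply(ex, function(e) e$logZ, 1))
    expected <- Reduce(`+`, lapply(ex, function(e) e$expected))
    ll <- sum(obs * w) + emis_ll - logZ - l2 / 2 * sum(w^2)
    if (!is.finite(ll)) stop("non-finite CRF objective; weights: ",
                             paste(signif(w, 4), collapse = ", "))
    list(value = ll, grad = obs - expected - l2 * w)
  }

  opt <- stats::optim(numeric(8),
                      fn = function(w) -obj_grad(w)$value,
                      gr = function(w) -obj_grad(w)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 1e7))
  w <- opt$par
  og <- obj_grad(w)
  structure(list(w = stats::setNames(w, crf_feature_names), D_max = D_max,
                 variant = variant, emission = emission, l2 = l2,
                 log_likelihood = og$value, iterations = opt$counts[["function"]],
                 grad_norm = max(abs(og$grad)), truncated = n_trunc),
            class = "fl_crf")
}

#' @export
print.fl_crf <- function(x, ...) {
  cat("<fl_crf (", x$variant, ", D_max=", x$D_max, "): ll=",
      signif(x$log_likelihood, 6), " after ", x$iterations, " iterations>\n",
      sep = "")
  print(round(x$w, 4))
  invisible(x)
}

#' CRF linkage scores for an article
#'
#' Computes per-step posteriors over subset states with forward-backward
#' and scores instance `(i, k)` by the posterior mass of states containing
#' sentence `i` at step `k`. Scores lie in `[0, 1]`.
#'
#' @param article An `fl_article`.
#' @param model An `fl_crf`.
#' @param S The article's score matrix (same kind as used in training).
#' @param posteriors Also return the full state posterior matrix?
#' @return Score matrix of kind `"CRF"`, or a list with `scores` and
#'   `state_posteriors` when `posteriors = TRUE`.
#' @export
predict_crf <- function(article, model, S, posteriors = FALSE) {
  ad <- crf_article_data(article, S, model$variant, model$D_max,
                         model$emission)
  str <- ad$structure
  w <- unname(model$w)
  logT <- matrix(str$Fflat %*% w, nrow(str$startF))
  fb <- crf_forward_backward(logT, as.vector(str$startF %*% w), ad$logE)
  lg <- fb$log_alpha + fb$log_beta - fb$logZ
  gamma <- exp(lg)
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  sc <- str$inc %*% gamma  # n x steps
  out <- if (model$variant == "sis") sc else t(sc)
  out <- fl_score_matrix(unname(as.matrix(out)), "CRF")
  if (posteriors) list(scores = out, state_posteriors = gamma,
                       states = str$states)
  else out
}
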