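#' Linkage-flow hidden Markov models
#'
#' The sentences-in-states (SIS) construction treats an article's figures as
#' the observation sequence (steps k = 1..n_f) and its abstract sentences as
#' states: state `q_i` (i >= 1) asserts that the current figure links with
#' sentence i, and the non-linked state `q_0` asserts it links with none. A
#' path through the chain therefore encodes a full linkage pattern in which
#' every figure links with 0 or 1 sentences, while a sentence may link with
#' any number of figures. The figures-in-states (FIS) variant swaps the two
#' roles (states are figures, steps are sentences) and is obtained here by
#' transposing inputs.
#'
#' Transition probabilities are learned once on a base structure sized to
#' the largest training article and restricted (or extended) to each test
#' article; emissions convert language-model scores into calibrated
#' per-state probabilities via class-conditional Gaussians.
#'
#' @name hmm
NULL

# linked state sets per observation step: list over steps of linked state
# indices (1-based sentences), or 0 when the step links nothing.
step_states <- function(L) {
  lapply(seq_len(ncol(L)), function(k) {
    s <- which(L[, k] == 1)
    if (length(s) == 0L) 0L else s
  })
}

#' Transition counts of the base HMM
#'
#' For every article and every consecutive step pair `(k-1, k)`, increments
#' `C[u, v]` for each state `u` occupied at step `k-1` and `v` at step `k`,
#' where the occupied states of a step are the sentences linked with that
#' figure (SIS), or the non-linked state 0 when there are none. Figures
#' linked with several sentences contribute all co-occurring pairs.
#'
#' @param corpus Training corpus with gold linkage.
#' @param variant `"sis"` or `"fis"`.
#' @return `(M_max + 1) x (M_max + 1)` integer count matrix; rows/columns
#'   indexed by state 0..M_max. `M_max` is the largest sentence (SIS) or
#'   figure (FIS) count in the corpus.
#' @export
transition_counts <- function(corpus, variant = c("sis", "fis")) {
  variant <- match.arg(variant)
  Ls <- lapply(corpus, function(a) {
    if (is.null(a$linkage)) stop("transition_counts() requires gold linkage")
    if (variant == "sis") a$linkage else t(a$linkage)
  })
  M <- max(vapply(Ls, nrow, 1L))
  C <- matrix(0L, M + 1L, M + 1L)
  for (L in Ls) {
    st <- step_states(L)
    for (k in seq_along(st)[-1]) {
      for (u in st[[k - 1]]) for (v in st[[k]])
        C[u + 1L, v + 1L] <- C[u + 1L, v + 1L] + 1L
    }
  }
  C
}

start_counts <- function(corpus, variant = c("sis", "fis")) {
  variant <- match.arg(variant)
  Ls <- lapply(corpus, function(a)
    if (variant == "sis") a$linkage else t(a$linkage))
  M <- max(vapply(Ls, nrow, 1L))
  cnt <- integer(M + 1L)
  for (L in Ls) for (u in step_states(L)[[1]]) cnt[u + 1L] <- cnt[u + 1L] + 1L
  cnt
}

#' MAP transition matrix from counts
#'
#' Dirichlet prior with all hyperparameters 1:
#' `A[u, v] = (C[u, v] + 1) / (sum_v C[u, v] + M_max + 1)`.
#'
#' @param C Non-negative count matrix.
#' @return Row-stochastic matrix of the same shape.
#' @export
map_transitions <- function(C) {
  if (any(C < 0)) stop("counts must be non-negative")
  (C + 1) / (rowSums(C) + ncol(C))
}

#' Fit a base HMM on a training corpus
#'
#' @inheritParams transition_counts
#' @param start How to set the initial state distribution: `"learned"`
#'   (Dirichlet-1 MAP over the state occupied at the first step of each
#'   training article) or `"uniform"`.
#' @return Object of class `fl_hmm`: `variant`, `M_max`, counts `C`, MAP
#'   transition matrix `A`, start counts and distribution.
#' @export
fit_hmm_base <- function(corpus, variant = c("sis", "fis"),
                         start = c("learned", "uniform")) {
  variant <- match.arg(variant); start <- match.arg(start)
  C <- transition_counts(corpus, variant)
  sc <- start_counts(corpus, variant)
  M <- nrow(C) - 1L
  pi0 <- if (start == "learned") (sc + 1) / (sum(sc) + M + 1)
         else rep(1 / (M + 1), M + 1)
  structure(list(variant = variant, M_max = M, C = C,
                 A = map_transitions(C), start_counts = sc, start = pi0),
            class = "fl_hmm")
}

#' Derive an article-sized HMM from the base structure
#'
#' For an article with `n` sentences (SIS) the derived chain has states
#' `q_0..q_n`. When `n <= M_max` the base transition matrix and start
#' distribution are restricted to those states and renormalized. When
#' `n > M_max` the count matrix is extended with zero counts (so new
#' transitions receive only their Dirichlet prior mass -- the "small
#' probabilities") and the MAP estimate is recomputed at the larger size.
#'
#' @param base An `fl_hmm`.
#' @param n Number of states excluding `q_0` (article sentence count for
#'   SIS).
#' @param B Optional `(n + 1) x n_steps` emission matrix attached to the
#'   result (rows = states 0..n).
#' @return Object of class `fl_hmm_derived` with `A` (`(n+1) x (n+1)` row
#'   stochastic), `start`, and `B` if given.
#' @export
derive_hmm <- function(base, n, B = NULL) {
  if (n < 1) stop("derived HMM needs n >= 1")
  M <- base$M_max
  if (n <= M) {
    idx <- seq_len(n + 1L)
    A <- base$A[idx, idx, drop = FALSE]
    A <- A / rowSums(A)
    start <- base$start[idx]; start <- start / sum(start)
  } else {
    C <- matrix(0L, n + 1L, n + 1L)
    C[seq_len(M + 1L), seq_len(M + 1L)] <- base$C
    A <- map_transitions(C)
    sc <- c(base$start_counts, integer(n - M))
    start <- (sc + 1) / (sum(sc) + n + 1)
  }
  structure(list(n = n, A = A, start = start, B = B),
            class = "fl_hmm_derived")
}

#' Gaussian calibration of linkage scores
#'
#' Sample mean and (unbiased) variance of instance scores for linked and for
#' non-linked training instances. A degenerate class variance is floored at
#' `eps` with a warning.
#'
#' @param z Numeric scores (language-model `S` or combined `Z`).
#' @param labels Binary gold labels, same length.
#' @param eps Variance floor.
#' @return Object of class `fl_emission`: `mu_linked`, `sd_linked`,
#'   `mu_unlinked`, `sd_unlinked`.
#' @export
fit_emission <- function(z, labels, eps = 1e-6) {
  if (sum(labels == 1) < 2L || sum(labels == 0) < 2L)
    stop("need >= 2 instances of each class")
  vfloor <- function(v, cls) {
    if (!is.finite(v) || v < eps) {
      warning("degenerate ", cls, " score variance; floored at ", eps)
      eps
    } else v
  }
  z1 <- z[labels == 1]; z0 <- z[labels == 0]
  structure(list(mu_linked = mean(z1),
                 sd_linked = sqrt(vfloor(stats::var(z1), "linked")),
                 mu_unlinked = mean(z0),
                 sd_unlinked = sqrt(vfloor(stats::var(z0), "unlinked"))),
            class = "fl_emission")
}

# log pdf ratio linked / unlinked at each score
emission_log_ratio <- function(z, em) {
  stats::dnorm(z, em$mu_linked, em$sd_linked, log = TRUE) -
    stats::dnorm(z, em$mu_unlinked, em$sd_unlinked, log = TRUE)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Emission probabilities for one observation step
#'
#' The step's observation is the score column `z[, k]`. Under state `q_i`
#' (i >= 1) score `z[i, k]` is drawn from the linked Gaussian and all other
#' scores from the unlinked Gaussian; under `q_0` all scores are unlinked.
#' Emission probabilities are these joint densities normalized over the
#' `n + 1` states, which reduces to a softmax of the per-sentence
#' log-density ratios (computed in log space).
#'
#' @param z_col Numeric vector of the step's scores (length `n`).
#' @param emission An `fl_emission`.
#' @return Probability vector over states `q_0..q_n` summing to 1.
#' @export
emission_matrix_column <- function(z_col, emission) {
  lr <- emission_log_ratio(z_col, emission)
  lw <- c(0, lr)  # relative to the all-unlinked state
  w <- exp(lw - log_sum_exp(lw))
  w / sum(w)
}

#' Emission matrix for an article
#'
#' @param Z `n x n_steps` score matrix (rows = states' entities).
#' @param emission An `fl_emission`.
#' @return `(n + 1) x n_steps` matrix; each column sums to 1.
#' @export
emission_matrix <- function(Z, emission) {
  apply(Z, 2, emission_matrix_column, emission = emission)
}

#' Posterior decoding of a derived HMM
#'
#' Forward-backward with per-step scaling. Returns the posterior probability
#' that the state occupied at step `k` is `q_i`, given the whole observation
#' sequence.
#'
#' @param hmm An `fl_hmm_derived` whose `B` emission matrix is set.
#' @param drop_q0 Drop the non-linked state row (the usual linkage score
#'   matrix)? Default `TRUE`.
#' @return `n x n_steps` (or `(n+1) x n_steps`) posterior matrix.
#' @export
posterior_decode <- function(hmm, drop_q0 = TRUE) {
  B <- hmm$B
  if (is.null(B)) stop("derived HMM has no emission matrix")
  n_states <- nrow(B); n_steps <- ncol(B)
  stopifnot(n_states == hmm$n + 1L)
  A <- hmm$A
  alpha <- matrix(0, n_states, n_steps)
  scale <- numeric(n_steps)
  a <- hmm$start * B[, 1]
  scale[1] <- sum(a); alpha[, 1] <- a / scale[1]
  if (n_steps > 1) for (k in 2:n_steps) {
    a <- as.vector(crossprod(A, alpha[, k - 1])) * B[, k]
    scale[k] <- sum(a)
    alpha[, k] <- a / scale[k]
  }
  beta <- matrix(0, n_states, n_steps)
  beta[, n_steps] <- 1
  if (n_steps > 1) for (k in (n_steps - 1):1) {
    b <- as.vector(A %*% (beta[, k + 1] * B[, k + 1]))
    beta[, k] <- b / scale[k + 1]
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  if (drop_q0) post[-1, , drop = FALSE] else post
}

#' Fit the full HMM linkage model
#'
#' Fits the base transition structure and the Gaussian emission calibration
#' from training scores.
#'
#' @param corpus Training corpus with gold linkage.
#' @param scores List of per-article score matrices (`S` or the combined
#'   `Z`; same order as `corpus`).
#' @param variant `"sis"` or `"fis"`.
#' @param start Initial-distribution scheme, see [fit_hmm_base()].
#' @return Object of class `fl_hmm_model` holding the base HMM and emission
#'   calibration.
#' @export
fit_hmm <- function(corpus, scores, variant = c("sis", "fis"),
                    start = c("learned", "uniform")) {
  variant <- match.arg(variant); start <- match.arg(start)
  base <- fit_hmm_base(corpus, variant, start)
  z <- unlist(lapply(scores, as.vector))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  em <- fit_emission(z, y)
  structure(list(base = base, emission = em, variant = variant),
            class = "fl_hmm_model")
}

#' HMM linkage scores for an article
#'
#' Builds the derived chain for the article, converts the article's score
#' matrix into emissions, and posterior-decodes. Scores are state-occupancy
#' posteriors in `[0, 1]`.
#'
#' @param article An `fl_article`.
#' @param model An `fl_hmm_model`.
#' @param S The article's `n_s x n_f` score matrix (same kind used at fit
#'   time).
#' @return `n_s x n_f` score matrix of kind `"H"`.
#' @export
predict_hmm <- function(article, model, S) {
  Z <- if (model$variant == "sis") unclass(S) else t(unclass(S))
  B <- emission_matrix(Z, model$emission)
  hm <- derive_hmm(model$base, nrow(Z), B)
  post <- posterior_decode(hm)
  H <- if (model$variant == "sis") post else t(post)
  fl_score_matrix(H, "H")
}
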