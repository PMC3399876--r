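# Independent brute-force oracles used by the unit and acceptance tests.
# They enumerate explicitly (paths, pairs, thresholds) and never reuse the
# package's dynamic-programming code paths.

# All state paths of length n_steps over states 1..n_states
all_paths <- function(n_states, n_steps) {
  grid <- do.call(expand.grid, rep(list(seq_len(n_states)), n_steps))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# HMM posteriors by explicit sum over every state path.
hmm_brute_posterior <- function(start, A, B) {
  n_states <- nrow(B); n_steps <- ncol(B)
  paths <- all_paths(n_states, n_steps)
  w <- vapply(paths, function(p) {
    pr <- start[p[1]] * B[p[1], 1]
    for (k in seq_len(n_steps)[-1]) pr <- pr * A[p[k - 1], p[k]] * B[p[k], k]
    pr
  }, 1)
  post <- matrix(0, n_states, n_steps)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (k in seq_len(n_steps)) post[p[k], k] <- post[p[k], k] + w[i]
  }
  sweep(post, 2, colSums(post), "/")
}

# CRF state posteriors and partition function by path enumeration.
crf_brute <- function(w, states, logE) {
  S <- length(states); K <- ncol(logE)
  paths <- all_paths(S, K)
  lw <- vapply(paths, function(p) {
    v <- sum(w * start_features(states[[p[1]]])) + logE[p[1], 1]
    for (k in seq_len(K)[-1])
      v <- v + sum(w * transition_features(states[[p[k - 1]]],
                                           states[[p[k]]])) + logE[p[k], k]
    v
  }, 1)
  pw <- exp(lw - max(lw))
  Z <- sum(pw)
  post <- matrix(0, S, K)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (k in seq_len(K)) post[p[k], k] <- post[p[k], k] + pw[i]
  }
  list(posteriors = sweep(post, 2, colSums(post), "/"),
       logZ = log(Z) + max(lw))
}

# AROC as the Mann-Whitney pairwise fraction (ties count half).
aroc_mann_whitney <- function(scores, gold) {
  pos <- scores[gold == 1]; neg <- scores[gold == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Maximum F1 by explicit sweep over every threshold.
max_f1_exhaustive <- function(scores, gold) {
  best <- 0
  for (th in unique(scores)) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred & gold); fp <- sum(pred & !gold); fn <- sum(!pred & gold)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    best <- max(best, f1)
  }
  best
}

# Crossed-edge count by explicit double loop over all links.
edges_crossed_brute <- function(L, j, k) {
  cnt <- 0L
  for (jj in seq_len(nrow(L))) for (kk in seq_len(ncol(L))) {
    if (L[jj, kk] == 1 &&
        ((jj < j && kk > k) || (jj > j && kk < k))) cnt <- cnt + 1L
  }
  cnt
}

# A tiny random article with gold links, for property tests.
random_article <- function(n_s, n_f, id = "rnd") {
  L <- matrix(rbinom(n_s * n_f, 1, 0.3), n_s, n_f)
  if (sum(L) == 0) L[sample(n_s, 1), sample(n_f, 1)] <- 1L
  words <- function(n) paste(sample(letters, n, replace = TRUE), collapse = " ")
  fl_article(id, vapply(seq_len(n_s), function(i) words(5), ""),
             lapply(seq_len(n_f), function(i)
               fl_figure(words(6), words(8))),
             L)
}
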