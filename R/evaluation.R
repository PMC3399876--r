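#' Precision, recall, false-positive rate and F1
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `FPR = FP / (FP + TN)`,
#' `F1 = 2RP / (R + P)`. When no instance is predicted positive, precision
#' is reported as 0 with a warning; F1 is 0 when `P + R = 0`.
#'
#' @param predicted,gold Binary vectors of equal length.
#' @return Named list `P`, `R`, `FPR`, `F1`.
#' @export
confusion_metrics <- function(predicted, gold) {
  if (length(predicted) != length(gold)) stop("length mismatch")
  tp <- sum(predicted == 1 & gold == 1)
  fp <- sum(predicted == 1 & gold == 0)
  fn <- sum(predicted == 0 & gold == 1)
  tn <- sum(predicted == 0 & gold == 0)
  P <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision reported as 0"); 0
  }
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  FPR <- if (fp + tn > 0) fp / (fp + tn) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, FPR = FPR, F1 = F1)
}

#' Recall-precision and ROC curves with AROC
#'
#' Thresholds are taken at the distinct score values (equal scores form one
#' threshold step). The ROC curve plots recall against false-positive rate;
#' AROC is its trapezoidal area, equal to the Mann-Whitney probability that
#' a random linked instance outscores a random unlinked one (ties counted
#' half). Label-independent (all-equal) scores give AROC exactly 0.5.
#'
#' @param scores Numeric scores.
#' @param gold Binary labels with at least one positive and one negative.
#' @return List: `roc` (data.frame `fpr`, `recall`), `pr` (data.frame
#'   `recall`, `precision`), `aroc`.
#' @export
curves_and_aroc <- function(scores, gold) {
  if (length(unique(gold)) < 2L)
    stop("curves require both a positive and a negative instance")
  pos <- sum(gold == 1); neg <- sum(gold == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- gold[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]; npred <- seq_along(y)[keep]
  fp <- npred - tp
  roc <- data.frame(fpr = c(0, fp / neg), recall = c(0, tp / pos))
  pr <- data.frame(recall = tp / pos, precision = tp / npred)
  aroc <- sum(diff(roc$fpr) * (roc$recall[-1] + roc$recall[-nrow(roc)]) / 2)
  list(roc = roc, pr = pr, aroc = aroc)
}

#' Precision at the reference operating point
#'
#' The operating point predicts as many linkages as there are abstract
#' sentences: per article, the top `n_s(a)` scoring instances of article
#' `a`; for the whole corpus, the top `sum_a n_s(a)` instances pooled. Ties
#' are broken deterministically by (article order, j, k).
#'
#' @param scores List of per-article score matrices.
#' @param corpus Corpus with gold linkage (same order).
#' @param mode `"per_article"` (mean of per-article precisions) or
#'   `"whole_corpus"`.
#' @return Precision value.
#' @export
precision_at_reference <- function(scores, corpus,
                                   mode = c("per_article", "whole_corpus")) {
  mode <- match.arg(mode)
  if (mode == "per_article") {
    ps <- mapply(function(S, a) {
      v <- as.vector(unclass(S)); y <- as.vector(a$linkage)
      top <- head(order(v, decreasing = TRUE), n_sentences(a))
      mean(y[top])
    }, scores, corpus)
    mean(ps)
  } else {
    v <- unlist(lapply(scores, function(S) as.vector(unclass(S))))
    y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
    n <- sum(vapply(corpus, n_sentences, 1L))
    top <- head(order(v, decreasing = TRUE), n)
    mean(y[top])
  }
}

#' Mean per-article maximum F1
#'
#' For each article, F1 is maximized over all score thresholds; the maxima
#' are averaged across articles. Articles with no gold links contribute 0
#' (configurable exclusion).
#'
#' @param scores List of per-article score matrices.
#' @param corpus Corpus with gold linkage.
#' @param drop_empty Exclude articles with no gold links instead of counting
#'   them as 0?
#' @return Mean of the per-article maxima.
#' @export
max_f1_per_article <- function(scores, corpus, drop_empty = FALSE) {
  f1s <- mapply(function(S, a) max_f1(as.vector(unclass(S)),
                                      as.vector(a$linkage)),
                scores, corpus)
  if (drop_empty) {
    haspos <- vapply(corpus, function(a) sum(a$linkage) > 0, TRUE)
    f1s <- f1s[haspos]
  }
  mean(f1s)
}

#' Whole-corpus maximum F1
#'
#' F1 maximized over a single threshold applied to all pooled instances.
#' Never exceeds the mean per-article maximum (which optimizes a threshold
#' per article).
#'
#' @inheritParams max_f1_per_article
#' @return Maximum pooled F1.
#' @export
max_f1_whole_corpus <- function(scores, corpus) {
  v <- unlist(lapply(scores, function(S) as.vector(unclass(S))))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  max_f1(v, y)
}

#' Mean clicks saved
#'
#' For a sentence whose last truly linked figure is figure `m` (document
#' order), a user reading figures sequentially clicks `m` times. If the
#' system's ranking of the figures for that sentence covers all its linked
#' figures within the top `r`, the user clicks `r` times, saving `m - r`.
#' Sentences with no links contribute 0. The mean is over all sentences of
#' all abstracts. Ranking ties are broken by figure document order.
#'
#' @param scores List of per-article score matrices.
#' @param corpus Corpus with gold linkage.
#' @return Mean clicks saved (can be negative if the ranking is worse than
#'   document order).
#' @export
clicks_saved <- function(scores, corpus) {
  per_sentence <- unlist(mapply(function(S, a) {
    L <- a$linkage
    vapply(seq_len(nrow(L)), function(j) {
      linked <- which(L[j, ] == 1)
      if (length(linked) == 0L) return(0)
      m <- max(linked)
      rk <- order(-unclass(S)[j, ], seq_len(ncol(L)))
      r <- max(match(linked, rk))
      m - r
    }, 1)
  }, scores, corpus, SIMPLIFY = FALSE))
  mean(per_sentence)
}

#' Permutation test for article effects
#'
#' Tests whether per-article performance exceeds what article identity
#' alone explains: instances are shuffled between articles while keeping
#' each article's instance count and linked-instance count fixed, and the
#' per-article mean AROC and precision-at-reference are recomputed for each
#' permutation.
#'
#' @param scores List of per-article score matrices.
#' @param corpus Corpus with gold linkage (>= 2 articles).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with achieved `per_article_aroc` / `per_article_precision`,
#'   the permutation null vectors, and the empirical ranks (fraction of
#'   permuted values below the achieved value).
#' @export
article_permutation_test <- function(scores, corpus, n_perm = 1000L,
                                     seed = 1L) {
  if (length(corpus) < 2L) stop("need >= 2 articles")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  v <- unlist(lapply(scores, function(S) as.vector(unclass(S))))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  sizes <- vapply(seq_along(corpus), function(i) length(scores[[i]]), 1L)
  n_s <- vapply(corpus, n_sentences, 1L)
  pos_per_article <- vapply(corpus, function(a) sum(a$linkage), 1L)

  eval_assignment <- function(vv, yy) {
    # vv, yy are pooled vectors already arranged so that consecutive blocks
    # of `sizes` belong to the articles
    off <- c(0L, cumsum(sizes))
    arocs <- numeric(length(sizes)); precs <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
      idx <- (off[i] + 1L):off[i + 1L]
      si <- vv[idx]; yi <- yy[idx]
      arocs[i] <- if (length(unique(yi)) < 2L) NA_real_
                  else curves_and_aroc(si, yi)$aroc
      precs[i] <- mean(yi[head(order(si, decreasing = TRUE), n_s[i])])
    }
    c(aroc = mean(arocs, na.rm = TRUE), prec = mean(precs))
  }

  achieved <- eval_assignment(v, y)
  restore <- local_rng(seed)
  on.exit(restore())
  null_aroc <- numeric(n_perm); null_prec <- numeric(n_perm)
  pos_idx <- which(y == 1); neg_idx <- which(y == 0)
  for (p in seq_len(n_perm)) {
    # assign each article its original number of linked and unlinked
    # instances, drawn without replacement from the pooled sets
    pos_pool <- sample(pos_idx); neg_pool <- sample(neg_idx)
    ord <- integer(0); po <- 1L; no <- 1L
    for (i in seq_along(sizes)) {
      np <- pos_per_article[i]; nn <- sizes[i] - np
      ord <- c(ord, pos_pool[seq_len(np) + po - 1L],
               neg_pool[seq_len(nn) + no - 1L])
      po <- po + np; no <- no + nn
    }
    r <- eval_assignment(v[ord], y[ord])
    null_aroc[p] <- r["aroc"]; null_prec[p] <- r["prec"]
  }
  list(per_article_aroc = unname(achieved["aroc"]),
       per_article_precision = unname(achieved["prec"]),
       null_aroc = null_aroc, null_precision = null_prec,
       rank_aroc = mean(null_aroc < achieved["aroc"]),
       rank_precision = mean(null_prec < achieved["prec"]))
}

#' Inter-annotator agreement statistics
#'
#' From a 2x2 contingency table of two annotators' link/non-link decisions:
#' percent agreement, Cohen's kappa, and each annotator's marginal link
#' rate.
#'
#' @param contingency 2x2 matrix; rows = annotator 1 (non-linked, linked),
#'   columns = annotator 2 (non-linked, linked).
#' @return List: `agreement`, `kappa`, `link_rate_rows`, `link_rate_cols`,
#'   `disagreement`.
#' @export
agreement_stats <- function(contingency) {
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2, 2))) stop("contingency must be 2x2")
  N <- sum(m)
  if (N == 0) stop("empty contingency table")
  po <- (m[1, 1] + m[2, 2]) / N
  row_m <- rowSums(m) / N; col_m <- colSums(m) / N
  pe <- sum(row_m * col_m)
  list(agreement = po,
       kappa = (po - pe) / (1 - pe),
       link_rate_rows = row_m[2], link_rate_cols = col_m[2],
       disagreement = 1 - po)
}

#' Paired t-test on per-article metrics of two systems
#'
#' Standard two-sided paired t-test. When the differences have zero
#' variance the p-value is reported as 1 with a warning.
#'
#' @param x,y Equal-length (>= 2) numeric vectors of per-article values.
#' @return List `p_value`, `t`, `mean_difference`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) stop("need equal lengths >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; p-value reported as 1")
    return(list(p_value = 1, t = NA_real_, mean_difference = mean(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       mean_difference = mean(d))
}

#' Evaluation report for one system's scores
#'
#' @param scores List of per-article score matrices.
#' @param corpus Corpus with gold linkage.
#' @return List with per-article and whole-corpus AROC, max F1,
#'   precision-at-reference, and mean clicks saved.
#' @export
eval_report <- function(scores, corpus) {
  v <- unlist(lapply(scores, function(S) as.vector(unclass(S))))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  per_aroc <- mapply(function(S, a) {
    yy <- as.vector(a$linkage)
    if (length(unique(yy)) < 2L) NA_real_
    else curves_and_aroc(as.vector(unclass(S)), yy)$aroc
  }, scores, corpus)
  list(whole_corpus = list(
         aroc = curves_and_aroc(v, y)$aroc,
         max_f1 = max_f1_whole_corpus(scores, corpus),
         precision = precision_at_reference(scores, corpus, "whole_corpus")),
       per_article = list(
         aroc = mean(per_aroc, na.rm = TRUE),
         max_f1 = max_f1_per_article(scores, corpus),
         precision = precision_at_reference(scores, corpus, "per_article")),
       clicks = clicks_saved(scores, corpus))
}
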