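#' Positional features of a sentence/figure instance
#'
#' `distance` is the difference of relative positions, `j / n_s - k / n_f`,
#' so a sentence and figure at the same relative depth in their respective
#' sequences have distance 0. The four indicators flag the first/last
#' sentence and figure.
#'
#' @param j,k 1-based sentence and figure indices.
#' @param n_s,n_f Sentence and figure counts of the article.
#' @return Named list: `distance`, `initial_sentence`, `last_sentence`,
#'   `initial_figure`, `last_figure`.
#' @export
positional_features <- function(j, k, n_s, n_f) {
  if (j < 1 || j > n_s || k < 1 || k > n_f)
    stop("index out of range: j=", j, " k=", k, " for n_s=", n_s, " n_f=", n_f)
  list(distance = j / n_s - k / n_f,
       initial_sentence = as.integer(j == 1),
       last_sentence = as.integer(j == n_s),
       initial_figure = as.integer(k == 1),
       last_figure = as.integer(k == n_f))
}

#' Linkage features of a sentence/figure instance
#'
#' Features derived from the rest of the article's linkage matrix.
#' `previous_sentence` is `L[j-1, k]`, `previous_figure` is `L[j, k-1]` and
#' `previous_sent_and_fig` is `L[j-1, k-1]`; each is `NA` where the previous
#' sentence or figure does not exist (j = 1 or k = 1) rather than silently 0.
#' `sentence_degree` and `figure_degree` count the other links of sentence
#' `j` and figure `k`. `edges_crossed` counts existing links `(j', k')` that
#' would cross the candidate edge `(j, k)` in the bipartite order diagram,
#' i.e. links with `j' < j, k' > k` or `j' > j, k' < k` -- links inconsistent
#' with preservation of relative ordering.
#'
#' @param L Binary `n_s x n_f` linkage matrix.
#' @param j,k 1-based indices of the candidate instance.
#' @return Named list of the six feature values (`NA` marks undefined).
#' @export
linkage_features <- function(L, j, k) {
  L <- as.matrix(L)
  if (!all(L %in% c(0, 1))) stop("linkage matrix must be binary")
  n_s <- nrow(L); n_f <- ncol(L)
  if (j < 1 || j > n_s || k < 1 || k > n_f) stop("index out of range")
  idx <- which(L == 1, arr.ind = TRUE)
  crossed <- sum((idx[, 1] < j & idx[, 2] > k) | (idx[, 1] > j & idx[, 2] < k))
  list(previous_sentence = if (j > 1) L[j - 1, k] else NA_integer_,
       previous_figure = if (k > 1) L[j, k - 1] else NA_integer_,
       previous_sent_and_fig = if (j > 1 && k > 1) L[j - 1, k - 1] else NA_integer_,
       sentence_degree = sum(L[j, -k]),
       figure_degree = sum(L[-j, k]),
       edges_crossed = as.integer(crossed))
}

#' Instance feature table for a corpus
#'
#' One row per sentence/figure instance with positional and (when gold
#' linkage is present) linkage features. Undefined previous-* features are
#' `NA`.
#'
#' @param corpus An `fl_corpus`.
#' @return A data.frame with columns `article_id`, `j`, `k`, the feature
#'   columns, and `linked` when gold linkage is available.
#' @export
feature_table <- function(corpus) {
  rows <- lapply(corpus, function(a) {
    n_s <- n_sentences(a); n_f <- n_figures(a)
    grid <- expand.grid(j = seq_len(n_s), k = seq_len(n_f))
    pos <- mapply(function(j, k) unlist(positional_features(j, k, n_s, n_f)),
                  grid$j, grid$k)
    df <- cbind(data.frame(article_id = a$article_id, j = grid$j, k = grid$k),
                as.data.frame(t(pos)))
    if (!is.null(a$linkage)) {
      lf <- mapply(function(j, k) unlist(linkage_features(a$linkage, j, k)),
                   grid$j, grid$k)
      df <- cbind(df, as.data.frame(t(lf)))
      df$linked <- a$linkage[cbind(grid$j, grid$k)]
    }
    df
  })
  do.call(rbind, rows)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

discretize_equal_freq <- function(x, n_bins) {
  qs <- stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                        names = FALSE, type = 7)
  findInterval(x, unique(qs)) + 1L
}

#' Percent information gain of a feature about the link label
#'
#' Mutual information between a (binned) feature and the binary label,
#' expressed as a percentage of the label entropy: 100 * [H(Y) - H(Y|X)] /
#' H(Y). 0% means not predictive, 100% completely predictive. Continuous
#' features (more distinct values than `n_bins`) are discretized into
#' equal-frequency bins; binary and small-integer features are used as-is.
#' `NA` feature values form their own category.
#'
#' @param feature_values Numeric vector.
#' @param labels Binary vector, same length, not all identical.
#' @param n_bins Number of equal-frequency bins for continuous features
#'   (default 10).
#' @return Percent gain in `[0, 100]`.
#' @export
percent_information_gain <- function(feature_values, labels, n_bins = 10L) {
  if (length(feature_values) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L)
    stop("labels are all identical; label entropy is 0")
  x <- feature_values
  xx <- x[!is.na(x)]
  if (length(unique(xx)) > n_bins) {
    x[!is.na(x)] <- discretize_equal_freq(xx, n_bins)
  }
  x <- addNA(factor(x), ifany = TRUE)
  tab <- table(x, labels)
  N <- sum(tab)
  hy <- entropy_nat(colSums(tab) / N)
  px <- rowSums(tab) / N
  hygx <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (px[i] == 0) return(0)
    px[i] * entropy_nat(tab[i, ] / sum(tab[i, ]))
  }, 1))
  100 * max(0, hy - hygx) / hy
}

#' Permutation p-value for percent information gain
#'
#' Shuffles the labels `n_perm` times and reports the add-one smoothed
#' fraction of permutations whose gain is at least the observed gain:
#' `(r + 1) / (n_perm + 1)`.
#'
#' @param feature_values,labels,n_bins As in [percent_information_gain()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `gain`, `p_value`, `n_perm`.
#' @export
gain_permutation_pvalue <- function(feature_values, labels, n_perm = 1000L,
                                    seed = 1L, n_bins = 10L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- percent_information_gain(feature_values, labels, n_bins)
  restore <- local_rng(seed)
  on.exit(restore())
  r <- 0L
  for (i in seq_len(n_perm)) {
    g <- percent_information_gain(feature_values, sample(labels), n_bins)
    if (g >= obs) r <- r + 1L
  }
  list(gain = obs, p_value = (r + 1) / (n_perm + 1), n_perm = n_perm)
}

# Seed the RNG locally; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
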