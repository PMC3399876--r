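#' Fit the binned distance model
#'
#' The Distance feature (`j / n_s - k / n_f`) is discretized into ten
#' equal-frequency bins whose boundaries are the deciles of all training
#' instances (linked and unlinked pooled). Within each bin the model holds
#' Laplace-smoothed class-conditional probabilities:
#' `p_linked[b] = (c_b^+ + 1) / (N^+ + 10)` and analogously for unlinked
#' instances. Bins are left-closed right-open; distances at prediction time
#' outside the training range clamp to the first/last bin.
#'
#' @param corpus Training corpus with gold linkage on every article.
#' @return Object of class `fl_dm` with `bin_edges` (9 interior boundaries),
#'   `p_linked`, `p_unlinked`.
#' @export
fit_dm <- function(corpus) {
  if (any(vapply(corpus, function(a) is.null(a$linkage), TRUE)))
    stop("fit_dm() requires gold linkage")
  d <- unlist(lapply(corpus, function(a) {
    n_s <- n_sentences(a); n_f <- n_figures(a)
    outer(seq_len(n_s) / n_s, seq_len(n_f) / n_f, "-")
  }))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  if (length(unique(d)) < 10L)
    stop("fewer than 10 distinct distance values; use a larger corpus")
  edges <- unique(stats::quantile(d, probs = seq_len(9) / 10,
                                  names = FALSE, type = 7))
  bins <- findInterval(d, edges) + 1L
  nb <- length(edges) + 1L
  cpos <- tabulate(bins[y == 1], nbins = nb)
  cneg <- tabulate(bins[y == 0], nbins = nb)
  structure(list(bin_edges = edges,
                 p_linked = (cpos + 1) / (sum(cpos) + nb),
                 p_unlinked = (cneg + 1) / (sum(cneg) + nb)),
            class = "fl_dm")
}

dm_bin <- function(model, d) findInterval(d, model$bin_edges) + 1L

#' Distance-model score matrix
#'
#' `D[j, k] = log(p_linked[bin] / p_unlinked[bin])` for the bin of the
#' instance's distance.
#'
#' @param article An `fl_article`.
#' @param model An `fl_dm` from [fit_dm()].
#' @return Score matrix of kind `"D"`.
#' @export
dm_score_matrix <- function(article, model) {
  n_s <- n_sentences(article); n_f <- n_figures(article)
  d <- outer(seq_len(n_s) / n_s, seq_len(n_f) / n_f, "-")
  b <- dm_bin(model, d)
  D <- matrix(log(model$p_linked[b] / model$p_unlinked[b]), n_s, n_f)
  fl_score_matrix(D, "D")
}

#' Combine language-model and distance-model scores
#'
#' Elementwise sum, `Z = S + D`: valid as a joint log-odds under the
#' assumption that sentence terms and distances are conditionally
#' independent given linkage status.
#'
#' @param S,D Score matrices of identical shape.
#' @return Score matrix of kind `"Z"`.
#' @export
combine_scores <- function(S, D) {
  if (!identical(dim(S), dim(D)))
    stop("shape mismatch: ", paste(dim(S), collapse = "x"), " vs ",
         paste(dim(D), collapse = "x"))
  fl_score_matrix(unclass(S) + unclass(D), "Z")
}
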