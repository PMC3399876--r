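#' Fit the full linkage-prediction model stack
#'
#' Fits, in order: the language model hyperparameters (by default the
#' complete model -- fixed-size background with a caption/referencing
#' mixture), the binned distance model, the Gaussian emission calibration on
#' the combined scores, and the requested HMM / CRF sequence models.
#'
#' @param corpus Training corpus; all articles need gold linkage.
#' @param figure_model,background_model Language-model kinds (see
#'   [fit_lm()]).
#' @param sequence_models Character vector among `"hmm_sis"`, `"hmm_fis"`,
#'   `"crf_sis"`, `"crf_fis"` (default: the two SIS models).
#' @param emission_scores Calibrate emissions on the combined `"Z"` scores
#'   (default) or the language-model `"S"` scores.
#' @param D_max CRF maximum sentences per state.
#' @param l2 CRF regularization strength.
#' @param ... Tokenizer options.
#' @return Object of class `fl_model` holding every fitted component.
#' @export
fl_fit <- function(corpus, figure_model = "mixture",
                   background_model = "fixed_size",
                   sequence_models = c("hmm_sis", "crf_sis"),
                   emission_scores = c("Z", "S"),
                   D_max = 2L, l2 = 1e-2, ...) {
  emission_scores <- match.arg(emission_scores)
  lm <- fit_lm(corpus, figure_model, background_model, ...)
  Ss <- lapply(corpus, predict_lm, model = lm, ...)
  dm <- fit_dm(corpus)
  Zs <- mapply(function(a, S) combine_scores(S, dm_score_matrix(a, dm)),
               corpus, Ss, SIMPLIFY = FALSE)
  seq_input <- if (emission_scores == "Z") Zs else Ss
  z <- unlist(lapply(seq_input, as.vector))
  y <- unlist(lapply(corpus, function(a) as.vector(a$linkage)))
  emission <- fit_emission(z, y)
  fits <- list()
  for (m in sequence_models) {
    variant <- sub("^(hmm|crf)_", "", m)
    fits[[m]] <- if (startsWith(m, "hmm"))
      fit_hmm(corpus, seq_input, variant)
    else
      train_crf(corpus, seq_input, variant, D_max = D_max,
                emission = emission, l2 = l2)
  }
  structure(list(lm = lm, dm = dm, emission = emission,
                 emission_scores = emission_scores,
                 sequence = fits, tokenizer = list(...)),
            class = "fl_model")
}

#' @export
print.fl_model <- function(x, ...) {
  cat("<fl_model>\n")
  print(x$lm)
  cat("  sequence models:", paste(names(x$sequence), collapse = ", "), "\n")
  invisible(x)
}

#' Score an article with any fitted method
#'
#' @param article An `fl_article` (gold linkage, if present, is ignored).
#' @param model An `fl_model` from [fl_fit()].
#' @param method One of `"lm"`, `"dm"`, `"lm_dm"`, `"hmm_sis"`,
#'   `"hmm_fis"`, `"crf_sis"`, `"crf_fis"`, `"tfidf"`.
#' @return Score matrix for the article.
#' @export
fl_score <- function(article, model,
                     method = c("crf_sis", "hmm_sis", "lm_dm", "lm", "dm",
                                "hmm_fis", "crf_fis", "tfidf")) {
  method <- match.arg(method)
  tok <- model$tokenizer
  S <- function() do.call(predict_lm, c(list(article, model$lm), tok))
  Z <- function() combine_scores(S(), dm_score_matrix(article, model$dm))
  seq_in <- function() if (model$emission_scores == "Z") Z() else S()
  switch(method,
    lm = S(),
    dm = dm_score_matrix(article, model$dm),
    lm_dm = Z(),
    tfidf = do.call(tfidf_baseline_score, c(list(article), tok)),
    hmm_sis = , hmm_fis = predict_hmm(article, model$sequence[[method]], seq_in()),
    crf_sis = , crf_fis = predict_crf(article, model$sequence[[method]], seq_in()))
}

#' Score every article of a corpus
#'
#' @inheritParams fl_score
#' @param corpus An `fl_corpus`.
#' @return List of score matrices.
#' @export
fl_score_corpus <- function(corpus, model, method = "crf_sis") {
  if (startsWith(method, "hmm") || startsWith(method, "crf")) {
    if (is.null(model$sequence[[method]]))
      stop("model was not fitted with sequence model '", method, "'")
  }
  lapply(corpus, fl_score, model = model, method = method)
}

#' Leave-one-article-out cross-validation
#'
#' For each article, fits the full stack on the remaining articles and
#' scores the held-out article, then evaluates the pooled out-of-fold
#' scores. All learnable parameters (lambda, beta, V, distance bins,
#' transition structure, Gaussian calibration, CRF weights) are re-fit in
#' every fold; the held-out article's text influences only its own
#' background and figure distributions, never the fitted parameters.
#'
#' @param corpus Corpus with gold linkage, >= 2 articles.
#' @param methods Methods to evaluate (see [fl_score()]).
#' @param ... Passed to [fl_fit()].
#' @return List with `scores` (method -> list of matrices in corpus order)
#'   and `report` (method -> [eval_report()] output).
#' @export
loao_crossval <- function(corpus, methods = c("lm", "lm_dm", "crf_sis"),
                          ...) {
  if (length(corpus) < 2L) stop("cross-validation needs >= 2 articles")
  seq_needed <- unique(methods[startsWith(methods, "hmm") |
                               startsWith(methods, "crf")])
  scores <- stats::setNames(rep(list(vector("list", length(corpus))), length(methods)),
                            methods)
  for (i in seq_along(corpus)) {
    train <- as_corpus(corpus[-i])
    fit <- fl_fit(train,
                  sequence_models = if (length(seq_needed)) seq_needed
                                    else character(0), ...)
    for (m in methods)
      scores[[m]][[i]] <- fl_score(corpus[[i]], fit, m)
  }
  report <- lapply(scores, eval_report, corpus = corpus)
  list(scores = scores, report = report)
}
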