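#' Synthetic annotated corpus generator
#'
#' Generates articles whose statistics emulate an author-annotated corpus of
#' full-text biomedical articles: roughly a third of abstract sentences link
#' no figure, links tend to preserve relative document order, and linked
#' sentences share vocabulary with their figures' captions and referencing
#' paragraphs. Each figure has a topic term distribution (symmetric
#' Dirichlet); captions are drawn from the topic, referencing paragraphs
#' from a topic/background mixture, and linked sentences draw each token
#' from the article background with probability `lambda_star` and otherwise
#' reuse a token of a linked figure's realized caption (with probability
#' `caption_fraction`) or referencing text -- exactly the background/figure
#' mixture the query-likelihood language model assumes and estimates, so
#' parameter-recovery tests are well-posed. Unlinked sentences are purely
#' background.
#'
#' Linkage is built by sampling per-sentence and per-figure link degrees
#' from the configured distributions (resampling until the totals match),
#' realizing them with an order-preserving slot matching, and then, with
#' probability `1 - order_preservation` per adjacent slot pair, swapping
#' slots to introduce crossing links.
#'
#' @param n_articles Number of articles.
#' @param n_s_range,n_f_range Inclusive ranges for sentence/figure counts.
#' @param vocab_size Vocabulary size.
#' @param background_concentration,topic_concentration Symmetric Dirichlet
#'   parameters of the article background and figure topic distributions
#'   (large = diffuse, small = sharp).
#' @param lambda_star Background token fraction of linked sentences (the
#'   quantity the language model's lambda estimates). `lambda_star = 1`
#'   removes all text signal.
#' @param caption_length,ref_length Token counts of captions and referencing
#'   paragraphs.
#' @param n_ref_range Range of referencing paragraphs per figure.
#' @param ref_topic_fraction Topic token fraction of referencing paragraphs.
#' @param caption_fraction Probability that a reused figure token of a
#'   linked sentence comes from the caption rather than the referencing
#'   text (the quantity the mixture model's beta estimates).
#' @param sentence_length_mean Mean extra Poisson length of sentences (plus
#'   a minimum of 4 tokens).
#' @param sentence_degree_probs,figure_degree_probs Probabilities of a
#'   sentence/figure having 0, 1, 2, 3 links (truncated at 3).
#' @param order_preservation Probability that relative link order is
#'   preserved at each adjacent slot pair (1 = no crossing links).
#' @param seed Integer seed; the corpus is deterministic given it.
#' @param max_tries Resampling cap for matching degree totals.
#' @return An `fl_corpus` with gold linkage; the generator configuration is
#'   attached as attribute `"config"`.
#' @export
generate_corpus <- function(n_articles,
                            n_s_range = c(6L, 10L),
                            n_f_range = c(4L, 9L),
                            vocab_size = 300L,
                            background_concentration = 5,
                            topic_concentration = 0.1,
                            lambda_star = 0.5,
                            caption_length = 40L,
                            ref_length = 80L,
                            n_ref_range = c(1L, 2L),
                            ref_topic_fraction = 0.8,
                            caption_fraction = 0.6,
                            sentence_length_mean = 9,
                            sentence_degree_probs = c(0.328, 0.384, 0.20, 0.088),
                            figure_degree_probs = c(0.123, 0.571, 0.22, 0.086),
                            order_preservation = 1,
                            seed = 1L,
                            max_tries = 500L) {
  stopifnot(abs(sum(sentence_degree_probs) - 1) < 1e-8,
            abs(sum(figure_degree_probs) - 1) < 1e-8,
            lambda_star >= 0, lambda_star <= 1,
            order_preservation >= 0, order_preservation <= 1)
  restore <- local_rng(seed)
  on.exit(restore())
  vocab <- sprintf("w%04d", seq_len(vocab_size))
  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  draw_text <- function(n, prob) paste(sample(vocab, n, replace = TRUE,
                                              prob = prob), collapse = " ")
  articles <- lapply(seq_len(n_articles), function(ai) {
    n_s <- sample(n_s_range[1]:n_s_range[2], 1)
    n_f <- sample(n_f_range[1]:n_f_range[2], 1)
    L <- sample_linkage(n_s, n_f, sentence_degree_probs, figure_degree_probs,
                        order_preservation, max_tries)
    bg <- rdirichlet(rep(background_concentration, vocab_size))
    # figure topics are re-weightings of the article background
    # (Dirichlet centred on it); topic_concentration * vocab_size controls
    # how sharply a topic concentrates relative to the background
    topics <- replicate(n_f,
                        rdirichlet(topic_concentration * vocab_size * bg),
                        simplify = FALSE)
    figures <- lapply(seq_len(n_f), function(k) {
      ref_mix <- ref_topic_fraction * topics[[k]] + (1 - ref_topic_fraction) * bg
      nref <- sample(n_ref_range[1]:n_ref_range[2], 1)
      fl_figure(caption = draw_text(caption_length, topics[[k]]),
                referencing_paragraphs = vapply(seq_len(nref), function(i)
                  draw_text(ref_length, ref_mix), ""))
    })
    # Token pools of the realized figure text: linked sentences reuse
    # figure wording, so their non-background tokens are drawn from the
    # empirical caption / referencing distributions -- the exact mixture
    # the language model assumes and estimates.
    cap_pool <- lapply(figures, function(f) tokenize(f$caption))
    ref_pool <- lapply(figures, function(f)
      unlist(lapply(f$referencing_paragraphs, tokenize), use.names = FALSE))
    sentences <- vapply(seq_len(n_s), function(j) {
      len <- 4L + stats::rpois(1, sentence_length_mean)
      linked <- which(L[j, ] == 1)
      if (length(linked) == 0L || lambda_star >= 1)
        return(draw_text(len, bg))
      # sentences are scored as sets of words, so draw DISTINCT terms:
      # each accepted term is independently background (prob lambda_star)
      # or reused figure wording, mirroring the model's mixture over a
      # sentence's distinct terms
      toks <- character(0)
      guard <- 0L
      while (length(toks) < len && guard < 50L * len) {
        guard <- guard + 1L
        tok <- if (stats::runif(1) < lambda_star) {
          sample(vocab, 1, prob = bg)
        } else {
          kf <- if (length(linked) == 1L) linked
                else linked[sample.int(length(linked), 1)]
          pool <- if (stats::runif(1) < caption_fraction ||
                      length(ref_pool[[kf]]) == 0L)
            cap_pool[[kf]] else ref_pool[[kf]]
          pool[sample.int(length(pool), 1)]
        }
        if (!(tok %in% toks)) toks <- c(toks, tok)
      }
      paste(toks, collapse = " ")
    }, "")
    fl_article(sprintf("synth-%03d", ai), sentences, figures, L)
  })
  corpus <- as_corpus(articles)
  attr(corpus, "config") <- list(
    n_articles = n_articles, n_s_range = n_s_range, n_f_range = n_f_range,
    vocab_size = vocab_size,
    background_concentration = background_concentration,
    topic_concentration = topic_concentration, lambda_star = lambda_star,
    caption_length = caption_length, ref_length = ref_length,
    n_ref_range = n_ref_range, ref_topic_fraction = ref_topic_fraction,
    caption_fraction = caption_fraction,
    sentence_length_mean = sentence_length_mean,
    sentence_degree_probs = sentence_degree_probs,
    figure_degree_probs = figure_degree_probs,
    order_preservation = order_preservation, seed = seed)
  corpus
}

# Choose which entity to repair: among candidates, pick one whose degree
# transition moves the empirical degree distribution closest to the target
# (greedy on the excess of the source bin minus the deficit of the
# destination bin). Ties broken at random.
pick_repair <- function(d, cand, target, up) {
  n <- length(d)
  emp <- tabulate(d + 1L, nbins = length(target)) / n
  excess <- emp - target
  gain <- vapply(cand, function(i) {
    from <- d[i] + 1L; to <- from + if (up) 1L else -1L
    excess[from] - excess[to]
  }, 1)
  best <- cand[gain >= max(gain) - 1e-12]
  if (length(best) == 1L) best else best[sample.int(length(best), 1)]
}

# Sample a linkage matrix with the given degree distributions and order
# preservation strength. Figure degrees are repaired toward the sentence
# degree total with random +/-1 adjustments (bounded by the support of the
# degree distribution), so the realized distribution stays close to the
# nominal one whatever the sentence/figure count imbalance.
sample_linkage <- function(n_s, n_f, sdeg_p, fdeg_p, preserve, max_tries) {
  degs <- 0:(length(sdeg_p) - 1L)
  dmax_f <- length(fdeg_p) - 1L
  for (try in seq_len(max_tries)) {
    ds <- sample(degs, n_s, replace = TRUE, prob = sdeg_p)
    ds <- pmin(ds, n_f)
    df <- sample(0:dmax_f, n_f, replace = TRUE, prob = fdeg_p)
    df <- pmin(df, n_s)
    if (sum(ds) == 0) next
    # reconcile the two totals with random +/-1 adjustments spread over
    # both sides, so neither marginal distribution absorbs all the drift
    guard <- 0L
    while (sum(df) != sum(ds) && guard < 1000L) {
      guard <- guard + 1L
      fig_short <- sum(df) < sum(ds)
      adjust_df <- stats::runif(1) < 0.5
      if (adjust_df) {
        cand <- if (fig_short) which(df < min(dmax_f, n_s)) else which(df > 0L)
        if (!length(cand)) next
        i <- pick_repair(df, cand, fdeg_p, up = fig_short)
        df[i] <- df[i] + if (fig_short) 1L else -1L
      } else {
        cand <- if (fig_short) which(ds > 0L)
                else which(ds < min(length(degs) - 1L, n_f))
        if (!length(cand)) next
        i <- pick_repair(ds, cand, sdeg_p, up = !fig_short)
        ds[i] <- ds[i] + if (fig_short) -1L else 1L
      }
    }
    if (sum(df) != sum(ds)) next
    # which sentence / figure carries which degree is exchangeable, so
    # permuting the assignments explores alternative monotone matchings
    # without touching the degree distribution; duplicate pairs (a sentence
    # matched twice to the same figure) reject only the permutation
    for (perm in 1:40) {
      ds_p <- sample(ds); df_p <- sample(df)
      slots_s <- rep(seq_len(n_s), ds_p)
      slots_f <- rep(seq_len(n_f), df_p)
      # order-preserving base matching, then local swaps for crossings
      if (preserve < 1 && length(slots_f) > 1) {
        for (i in seq_len(length(slots_f) - 1L)) {
          if (stats::runif(1) > preserve)
            slots_f[c(i, i + 1L)] <- slots_f[c(i + 1L, i)]
        }
      }
      pairs <- cbind(slots_s, slots_f)
      if (anyDuplicated(pairs)) next
      L <- matrix(0L, n_s, n_f)
      L[pairs] <- 1L
      return(L)
    }
  }
  stop("could not realize compatible link degrees after ", max_tries,
       " tries; relax the degree distributions")
}

#' Small hand-checkable fixture articles
#'
#' Three tiny articles with known structure, used throughout the test
#' suite:
#' \describe{
#'   \item{order-example}{4 sentences x 3 figures with 4 links
#'     (`(1,1), (1,2), (2,3), (4,3)`), exhibiting both order-preserving and
#'     order-violating candidate edges.}
#'   \item{path-example}{3 sentences x 5 figures whose linkage
#'     `(2,1), (2,3), (3,4)` is exactly the pattern asserted by the SIS HMM
#'     state path (q2, q0, q2, q3, q0): figures 2 and 5 link nothing.}
#'   \item{tiny-lm}{2 sentences x 2 figures with single-character terms and
#'     hand-computable language-model scores.}
#' }
#'
#' @return An `fl_corpus` of the three articles.
#' @export
golden_fixtures <- function() {
  a <- fl_article(
    "order-example",
    sentences = c("alpha beta", "gamma delta", "epsilon zeta", "eta theta"),
    figures = list(
      fl_figure("alpha beta caption", "alpha beta body"),
      fl_figure("alpha caption two", "beta body two"),
      fl_figure("gamma eta caption", "delta theta body")),
    linkage = matrix(c(1, 0, 0, 0,
                       1, 0, 0, 0,
                       0, 1, 0, 1), nrow = 4))
  b <- fl_article(
    "path-example",
    sentences = c("one alpha", "two beta", "three gamma"),
    figures = list(
      fl_figure("beta figure", character(0)),
      fl_figure("unlinked figure", character(0)),
      fl_figure("beta again", character(0)),
      fl_figure("gamma figure", character(0)),
      fl_figure("also unlinked", character(0))),
    linkage = matrix(c(0, 1, 0,
                       0, 0, 0,
                       0, 1, 0,
                       0, 0, 1,
                       0, 0, 0), nrow = 3))
  cc <- fl_article(
    "tiny-lm",
    sentences = c("x y", "z z q"),
    figures = list(
      fl_figure("x x y", "y z"),
      fl_figure("q", character(0))),
    linkage = matrix(c(1, 0, 0, 1), nrow = 2))
  as_corpus(list(a, b, cc))
}
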