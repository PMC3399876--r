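tiny <- golden_fixtures()[[3]]  # "tiny-lm": sentences "x y" / "z z q"

test_that("figure-specific term distributions are source frequencies", {
  fc <- figure_counts(fl_figure("x x y", "y z"))
  p_cap <- figure_term_prob(fc, "caption_only")
  expect_equal(p_cap[["x"]], 2 / 3)
  expect_equal(p_cap[["y"]], 1 / 3)
  expect_equal(sum(p_cap), 1)

  # mixture with beta = 1 collapses to the caption distribution
  p_mix1 <- figure_term_prob(fc, "mixture", beta = 1)
  expect_equal(p_mix1[names(p_cap)], p_cap)

  fc2 <- figure_counts(fl_figure("a", c("a b", "b b")))
  p_pool <- figure_term_prob(fc2, "pooled")  # counts a: 1+1, b: 3
  expect_equal(p_pool[["a"]], 2 / 5)
  expect_equal(p_pool[["b"]], 3 / 5)

  # mixture weights the two source distributions
  p_mix <- figure_term_prob(fc, "mixture", beta = 0.5)
  expect_equal(p_mix[["x"]], 0.5 * 2 / 3)
  expect_equal(p_mix[["z"]], 0.5 * 1 / 2)
  expect_equal(p_mix[["y"]], 0.5 * 1 / 3 + 0.5 * 1 / 2)

  # empty chosen source falls back with a warning
  fc3 <- figure_counts(fl_figure("", "only refs here"))
  expect_warning(p <- figure_term_prob(fc3, "caption_only"), "falling back")
  expect_equal(sum(p), 1)
  # both sources empty: all mass to the background
  fc4 <- figure_counts(fl_figure("", character(0)))
  expect_length(figure_term_prob(fc4, "mixture", beta = 0.5), 0)
})

test_that("background distributions use add-one smoothing over the pool", {
  art <- fl_article("bg", c("a a a", "b"), list(fl_figure("", character(0))))
  bg_var <- background_prob(art, "variable_size")
  expect_equal(bg_var$prob[["a"]], 4 / 6)
  expect_equal(bg_var$prob[["b"]], 2 / 6)
  expect_equal(bg_var$unseen, 0)

  bg_fix <- background_prob(art, "fixed_size", V = 10)
  expect_equal(bg_fix$prob[["a"]], 4 / 14)
  expect_equal(bg_fix$prob[["b"]], 2 / 14)
  expect_equal(bg_fix$unseen, 1 / 14)
  # total mass over the implicit V-term vocabulary is 1
  expect_equal(sum(bg_fix$prob) + (10 - bg_fix$V_d) * bg_fix$unseen, 1)

  expect_error(background_prob(art, "fixed_size", V = 1), "smaller")
})

test_that("the log-odds score matches hand arithmetic and degenerate cases", {
  # lambda = 1: mixture collapses to the background, score 0
  expect_equal(lm_score(c(q = 1L), c(q = 0.5), c(q = 0.1), lambda = 1), 0)
  # hand example: log((0.5*0.1 + 0.5*0.5) / 0.1) = log 3
  expect_equal(lm_score(c(q = 1L), c(q = 0.5), c(q = 0.1), lambda = 0.5),
               log(3))
  expect_equal(lm_score(setNames(integer(0), character(0)),
                        c(q = 0.5), c(q = 0.1), 0.5), 0)
  # additivity over disjoint term sets
  fig <- c(a = 0.4, b = 0.6); bg <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(lm_score(c(a = 1L, b = 1L), fig, bg, 0.7),
               lm_score(c(a = 1L), fig, bg, 0.7) +
                 lm_score(c(b = 1L), fig, bg, 0.7))
  # zero-background guard is capped with a warning
  expect_warning(s <- lm_score(c(z = 1L), c(z = 0.5), c(q = 1), 0.5), "capped")
  expect_true(is.finite(s))
})

test_that("article score matrices match per-instance hand computation", {
  lam <- 0.5; bet <- 0.7
  S <- score_article(tiny, "mixture", "variable_size", lambda = lam, beta = bet)
  expect_equal(dim(S), c(2, 2))
  bg <- background_prob(tiny, "variable_size")
  figs <- lapply(tiny$figures, function(f)
    suppressWarnings(figure_term_prob(figure_counts(f), "mixture", beta = bet)))
  for (j in 1:2) for (k in 1:2) {
    sv <- sentence_vector(tiny$sentences[[j]])
    expect_equal(S[j, k], suppressWarnings(lm_score(sv, figs[[k]], bg, lam)))
  }
  # figure order equivariance and duplicate figures
  perm <- fl_article("p", tiny$sentences, tiny$figures[c(2, 1)])
  Sp <- score_article(perm, "mixture", "variable_size", lambda = lam, beta = bet)
  expect_equal(unclass(Sp), unclass(S)[, c(2, 1)], ignore_attr = TRUE)
  dup <- fl_article("d", tiny$sentences, tiny$figures[c(1, 1)])
  Sd <- score_article(dup, "mixture", "variable_size", lambda = lam, beta = bet)
  expect_equal(Sd[, 1], Sd[, 2])
})

test_that("hyperparameter search uses the prescribed grids and objectives", {
  co <- generate_corpus(8, seed = 31)
  fit_v <- fit_lm(co, "caption_only", "variable_size")
  expect_length(fit_v$diagnostics$search$grid, 99)
  expect_equal(fit_v$diagnostics$search$grid,
               seq(0.01, 0.99, by = 0.01))
  # fitted lambda attains the grid maximum
  expect_equal(max(fit_v$diagnostics$search$values),
               fit_v$diagnostics$search$values[
                 match(fit_v$lambda, fit_v$diagnostics$search$grid)])

  fit_m <- fit_lm(co, "mixture", "fixed_size")
  expect_equal(nrow(fit_m$diagnostics$search$grid), 120)
  expect_true(all(fit_m$diagnostics$search$grid > 0 &
                  fit_m$diagnostics$search$grid < 1))
  # V minimizes |cor(length, score)| on its grid, so it is no worse than
  # the smallest admissible vocabulary
  vs <- fit_m$diagnostics$v_search
  expect_equal(vs$cor_at_V, min(vs$cors))
  expect_lte(vs$cor_at_V, vs$cors[1])
  expect_error(fit_lm(structure(list(fl_article("x", "s",
                                                list(fl_figure("c")))),
                                class = "fl_corpus"),
                      "caption_only", "variable_size"),
               "gold linkage")
})

test_that("the TFIDF baseline computes article-level cosines", {
  art <- fl_article("t", c("alpha beta gamma", "delta delta"),
                    list(fl_figure("alpha beta gamma", character(0)),
                         fl_figure("zeta eta", character(0))))
  S <- tfidf_baseline_score(art)
  expect_equal(S[1, 1], 1)          # identical texts
  expect_equal(S[2, 1], 0)          # disjoint vocabularies
  expect_equal(S[2, 2], 0)
  # hand-computed cosine for a shared-term pair
  art2 <- fl_article("t2", c("a b"),
                     list(fl_figure("a c", character(0))))
  # docs: {a b}, {a c}; df(a)=2, df(b)=df(c)=1; idf(a)=0 -> only
  # zero-weighted overlap, cosine 0
  expect_equal(tfidf_baseline_score(art2)[1, 1], 0)
  art3 <- fl_article("t3", c("a b", "c d"),
                     list(fl_figure("a b", character(0)),
                          fl_figure("d e", character(0))))
  S3 <- tfidf_baseline_score(art3)
  # sentence 2 vs figure 2 share only term d: cosine =
  # idf(d)^2 / (sqrt(idf(c)^2+idf(d)^2) * sqrt(idf(d)^2+idf(e)^2))
  idf <- log(4 / c(c = 1, d = 2, e = 1))
  expect_equal(S3[2, 2], idf[["d"]]^2 /
                 (sqrt(idf[["c"]]^2 + idf[["d"]]^2) *
                  sqrt(idf[["d"]]^2 + idf[["e"]]^2)))
})
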