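mk1 <- function(L, id = "a") {
  fl_article(id, paste("s", seq_len(nrow(L))),
             lapply(seq_len(ncol(L)), function(k) fl_figure(paste("f", k))),
             L)
}

test_that("confusion metrics implement the standard definitions", {
  # annotator contingency read as predictions vs gold:
  # TP = 57, FP = 58, FN = 22, TN = 283
  pred <- c(rep(1, 57), rep(1, 58), rep(0, 22), rep(0, 283))
  gold <- c(rep(1, 57), rep(0, 58), rep(1, 22), rep(0, 283))
  m <- confusion_metrics(pred, gold)
  expect_equal(m$P, 57 / 115)
  expect_equal(m$R, 57 / 79)
  expect_equal(m$F1, 2 * m$P * m$R / (m$P + m$R))

  p <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(p$P, p$R, p$F1), c(1, 1, 1))
  expect_warning(n <- confusion_metrics(c(0, 0), c(1, 0)), "precision")
  expect_equal(n$R, 0)
  expect_equal(n$F1, 0)
})

test_that("AROC matches the Mann-Whitney oracle and handles ties", {
  expect_equal(curves_and_aroc(c(3, 2, 1, 0), c(1, 1, 0, 0))$aroc, 1)
  # label-independent scores: exactly 0.5 under the tie convention
  expect_equal(curves_and_aroc(rep(1, 6), c(1, 0, 1, 0, 0, 1))$aroc, 0.5)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    s <- sample(1:5, n, replace = TRUE)  # forced ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(curves_and_aroc(s, y)$aroc, aroc_mann_whitney(s, y))
  }
  expect_error(curves_and_aroc(1:3, c(1, 1, 1)), "positive and a negative")
})

test_that("precision at the reference point selects top n_s instances", {
  a1 <- mk1(matrix(c(1, 0, 0, 1), 2, 2), "a1")
  a2 <- mk1(matrix(c(1, 0, 0, 0, 1, 0), 3, 2), "a2")
  co <- structure(list(a1, a2), class = "fl_corpus")
  s1 <- matrix(c(5, 1, 2, 4), 2, 2)    # top-2: (1,1) and (2,2), both linked
  s2 <- matrix(c(6, 1, 2, 5, 3, 0), 3, 2)  # top-3: (1,1), (2,2)=1, (3,2)? ->
  sc <- list(s1, s2)
  expect_equal(precision_at_reference(sc, co, "per_article"),
               mean(c(1, mean(c(1, 1, 0)))))
  # whole corpus: top 5 of all 10 instances
  v <- c(as.vector(s1), as.vector(s2))
  y <- c(as.vector(a1$linkage), as.vector(a2$linkage))
  expect_equal(precision_at_reference(sc, co, "whole_corpus"),
               mean(y[order(v, decreasing = TRUE)][1:5]))
})

test_that("per-article maximum F1 equals an exhaustive threshold sweep", {
  a <- mk1(matrix(c(1, 0, 1, 0, 1, 0), 3, 2))
  S <- matrix(c(0.9, 0.2, 0.8, 0.3, 0.7, 0.1), 3, 2)
  co <- structure(list(a), class = "fl_corpus")
  expect_equal(max_f1_per_article(list(S), co),
               max_f1_exhaustive(as.vector(S), as.vector(a$linkage)))
  # perfectly ranked article
  ap <- mk1(matrix(c(1, 0, 0, 0), 2, 2))
  Sp <- matrix(c(4, 1, 2, 3), 2, 2) * 0 + matrix(c(9, 1, 2, 3), 2, 2)
  expect_equal(max_f1_per_article(list(Sp), structure(list(ap),
                                                      class = "fl_corpus")), 1)
  # duplicate scores collapse to one threshold
  ad <- mk1(matrix(c(1, 1, 0, 0), 2, 2))
  Sd <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(max_f1_per_article(list(Sd), structure(list(ad),
                                                      class = "fl_corpus")), 1)
})

test_that("whole-corpus maximum F1 does not exceed the per-article mean", {
  # the per-article mean optimizes a threshold within each article and so
  # systematically dominates the single pooled threshold on evaluated
  # corpora of realistic size
  for (i in 1:5) {
    co <- generate_corpus(12, seed = 860 + i)
    sc <- lapply(co, score_article, figure_model = "pooled",
                 background_model = "variable_size", lambda = 0.8)
    expect_lte(max_f1_whole_corpus(sc, co),
               max_f1_per_article(sc, co) + 1e-12)
  }
})

test_that("clicks saved follow the last-linked-figure model", {
  # sentence linked only to figure 5, ranked first by the system: saves 4
  a <- mk1(matrix(c(0, 0, 0, 0, 1), 1, 5))
  S <- matrix(c(1, 2, 3, 4, 9), 1, 5)
  co <- structure(list(a), class = "fl_corpus")
  expect_equal(clicks_saved(list(S), co), 4)
  # ranking equal to document order saves nothing
  Sdoc <- matrix(5:1, 1, 5)
  expect_equal(clicks_saved(list(Sdoc), co), 0)
  # sentences without links contribute zero to the mean
  b <- mk1(rbind(c(0, 0, 0, 0, 1), rep(0, 5)))
  expect_equal(clicks_saved(list(rbind(S, S)),
                            structure(list(b), class = "fl_corpus")), 2)
  # document-order ranking is always zero
  set.seed(6)
  for (i in 1:8) {
    a <- random_article(3, 4)
    co <- structure(list(a), class = "fl_corpus")
    Sdoc <- matrix(rep(4:1, each = 3), 3, 4)
    expect_equal(clicks_saved(list(Sdoc), co), 0)
  }
})

test_that("the article permutation test is calibrated and reproducible", {
  co <- generate_corpus(6, seed = 44)
  sc <- lapply(co, function(a) matrix(rnorm(length(a$linkage)),
                                      nrow(a$linkage)))
  r1 <- article_permutation_test(sc, co, n_perm = 200, seed = 9)
  r2 <- article_permutation_test(sc, co, n_perm = 200, seed = 9)
  expect_identical(r1$null_aroc, r2$null_aroc)
  # label-independent scores: achieved value inside the null bulk
  expect_gt(r1$rank_aroc, 0.005)
  expect_lt(r1$rank_aroc, 0.995)
  expect_error(article_permutation_test(sc, co, n_perm = 0), "n_perm")
})

test_that("agreement statistics reproduce contingency-table arithmetic", {
  tab <- matrix(c(283, 58, 22, 57), 2, 2)  # rows: annotator A, cols: B
  ag <- agreement_stats(tab)
  expect_equal(ag$agreement, 340 / 420)
  expect_equal(ag$disagreement, 80 / 420)
  po <- 340 / 420
  pe <- (305 / 420) * (341 / 420) + (115 / 420) * (79 / 420)
  expect_equal(ag$kappa, (po - pe) / (1 - pe))
  expect_equal(unname(ag$link_rate_rows), 115 / 420)

  expect_equal(agreement_stats(matrix(c(10, 0, 0, 10), 2, 2))$kappa, 1)
  # independent marginals: kappa 0
  expect_equal(agreement_stats(matrix(c(16, 4, 4, 1), 2, 2))$kappa, 0)
  expect_error(agreement_stats(matrix(0, 2, 2)), "empty")
})

test_that("paired t-tests match the closed form and warn on zero variance", {
  x <- c(0.61, 0.55, 0.70, 0.64, 0.58)
  y <- c(0.52, 0.50, 0.66, 0.60, 0.49)
  r <- paired_ttest(x, y)
  d <- x - y
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, tstat)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 4))
  expect_warning(rz <- paired_ttest(x, x), "zero variance")
  expect_equal(rz$p_value, 1)
  r2 <- paired_ttest(1:10 + 0.5, 1:10 + 0.4 + rnorm(10, 0, 1e-9))
  expect_lt(r2$p_value, 0.001)
})

test_that("leave-one-article-out cross-validation isolates folds", {
  co <- generate_corpus(4, seed = 55)
  cv <- suppressMessages(loao_crossval(co, methods = c("lm", "lm_dm")))
  expect_length(cv$scores$lm, 4)
  for (i in 1:4)
    expect_equal(dim(cv$scores$lm[[i]]),
                 c(length(co[[i]]$sentences), length(co[[i]]$figures)))
  expect_true(all(is.finite(unlist(cv$report$lm))))
  expect_true(all(is.finite(unlist(cv$report$lm_dm))))
  # perturbing a held-out article's text does not change the parameters
  # fitted on the remaining articles
  f_before <- fit_lm(structure(co[-2], class = "fl_corpus"),
                     "mixture", "fixed_size")
  co2 <- co
  co2[[2]]$sentences <- rev(co2[[2]]$sentences)
  f_after <- fit_lm(structure(co2[-2], class = "fl_corpus"),
                    "mixture", "fixed_size")
  expect_identical(f_before$lambda, f_after$lambda)
  expect_identical(f_before$V, f_after$V)
  expect_error(loao_crossval(structure(co[1], class = "fl_corpus")), ">= 2")
})
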