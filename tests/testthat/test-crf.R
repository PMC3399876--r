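unit_em <- structure(list(mu_linked = 1, sd_linked = 1,
                          mu_unlinked = 0, sd_unlinked = 1),
                     class = "fl_emission")

test_that("state enumeration covers all subsets up to D_max in canonical order", {
  s <- enumerate_states(4, 2)
  expect_length(s, 1 + 4 + 6)
  expect_identical(s[[1]], integer(0))
  expect_identical(s[[2]], 1L)
  sizes <- vapply(s, length, 1L)
  expect_true(all(diff(sizes) >= 0))  # ordered by size
  expect_identical(enumerate_states(1, 2), list(integer(0), 1L))
  expect_length(enumerate_states(3, 3), 8)  # full power set
})

test_that("transition features match their definitions", {
  f0 <- transition_features(integer(0), integer(0))
  expect_equal(unname(f0), c(1, 0, 0, 0, 0, 0, 0, 0))

  f1 <- transition_features(1L, 1L)
  expect_equal(f1[["FigureDegree1"]], 1)
  expect_equal(f1[["PreviousFigure"]], 1)
  expect_equal(f1[["EdgesCrossed"]], 0)
  expect_equal(sum(f1), 2)

  f2 <- transition_features(2L, c(1L, 3L))
  expect_equal(f2[["FigureDegree2"]], 1)
  expect_equal(f2[["EdgesCrossed"]], 1)      # source 2 > destination 1
  expect_equal(f2[["PrevSentAndFig"]], 1)    # 3 follows 2
  expect_equal(f2[["PreviousSentence"]], 0)
  expect_equal(f2[["PreviousFigure"]], 0)

  # EdgesCrossed against brute-force pair checking
  set.seed(12)
  for (i in 1:20) {
    A <- sort(sample(1:6, sample(0:2, 1)))
    Ad <- sort(sample(1:6, sample(0:2, 1)))
    brute <- 0
    for (ii in Ad) for (ip in A) if (ip > ii) brute <- brute + 1
    expect_equal(transition_features(A, Ad)[["EdgesCrossed"]], brute)
  }
})

test_that("start features are transition features from an empty source", {
  s0 <- start_features(integer(0))
  expect_equal(s0[["FigureDegree0"]], 1)
  expect_equal(sum(s0), 1)
  s12 <- start_features(c(1L, 2L))
  expect_equal(s12[["FigureDegree2"]], 1)
  expect_equal(s12[["PreviousSentence"]], 1)
  expect_equal(s12[["PreviousFigure"]], 0)
  expect_equal(s12[["PrevSentAndFig"]], 0)
  expect_equal(s12[["EdgesCrossed"]], 0)
})

test_that("emission affinities generalize the HMM emissions to subset states", {
  states2 <- enumerate_states(2, 2)
  Z <- matrix(c(0.4, 1.3), 2, 1)
  E <- emission_affinities(Z, unit_em, states2)
  # log ratios r_i = z_i - 1/2; affinities prop to (1, e^{r1}, e^{r2}, e^{r1+r2})
  r <- Z[, 1] - 0.5
  expect_equal(E[, 1], exp(c(0, r[1], r[2], r[1] + r[2])) /
                 sum(exp(c(0, r[1], r[2], r[1] + r[2]))))
  # identical Gaussians: uniform over states
  em0 <- unit_em; em0$mu_linked <- 0
  expect_true(all(abs(emission_affinities(Z, em0, states2) - 1 / 4) < 1e-12))
  # n_s = 1 reduces to the HMM emission column
  states1 <- enumerate_states(1, 2)
  z1 <- matrix(0.7, 1, 1)
  expect_equal(emission_affinities(z1, unit_em, states1)[, 1],
               emission_matrix_column(0.7, unit_em))
  # columns sum to one
  E2 <- emission_affinities(matrix(rnorm(6), 2, 3), unit_em, states2)
  expect_equal(colSums(E2), rep(1, 3))
})

test_that("path scores multiply start, emission and transition affinities", {
  states <- enumerate_states(2, 2)
  E <- matrix(1 / 4, 4, 2)
  # w = 0: all paths carry the same weight
  w0 <- numeric(8)
  weights <- vapply(all_paths(4, 2), function(p)
    path_unnormalized_prob(list(states[[p[1]]], states[[p[2]]]), w0, E, states),
    1)
  expect_true(all(abs(weights - weights[1]) < 1e-12))
  # hand product on a 2-step toy
  w <- c(0.1, -0.2, 0.3, 0, 0.5, -0.4, 0.2, 0.1)
  p <- list(1L, c(1L, 2L))
  expect_equal(path_unnormalized_prob(p, w, E, states),
               exp(sum(w * start_features(1L)) +
                   sum(w * transition_features(1L, c(1L, 2L)))) *
                 E[2, 1] * E[4, 2])
  # single-figure article: start affinity times one emission
  expect_equal(path_unnormalized_prob(list(2L), w,
                                      matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1),
                                      states),
               exp(sum(w * start_features(2L))) * 0.3)
})

test_that("forward-backward equals brute-force enumeration and is consistent", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:3, 1); K <- sample(1:3, 1)
    states <- enumerate_states(n, 2)
    S <- length(states)
    w <- rnorm(8) / 2
    logE <- matrix(log(matrix(rgamma(S * K, 1), S)), S)
    logE <- sweep(logE, 2, apply(logE, 2, figlink:::log_sum_exp))
    str <- figlink:::crf_structure(n, 2)
    logT <- matrix(str$Fflat %*% w, S)
    fb <- figlink:::crf_forward_backward(logT, as.vector(str$startF %*% w), logE)
    oracle <- crf_brute(w, states, logE)
    expect_equal(fb$logZ, oracle$logZ, tolerance = 1e-8)
    # forward and backward partition estimates agree
    expect_equal(fb$logZ, fb$logZ_backward, tolerance = 1e-8)
    post <- exp(fb$log_alpha + fb$log_beta - fb$logZ)
    expect_equal(post, oracle$posteriors, tolerance = 1e-8)
  }
})

test_that("the analytic gradient matches central finite differences", {
  co <- structure(list(
    fl_article("g", c("a b", "c d", "e f"),
               list(fl_figure("a b"), fl_figure("c d")),
               matrix(c(1, 0, 0, 0, 1, 1), 3, 2))),
    class = "fl_corpus")
  S <- matrix(c(1.2, -0.3, 0.1, -0.5, 0.8, 0.6), 3, 2)
  ad <- figlink:::crf_article_data(co[[1]], S, "sis", 2, unit_em)
  obs <- figlink:::crf_observed(ad)
  emis_ll <- sum(ad$logE[cbind(ad$path_idx, 1:2)])
  ll <- function(w) {
    ex <- figlink:::crf_expected(ad, w)
    sum(obs * w) + emis_ll - ex$logZ
  }
  w0 <- c(0.2, -0.1, 0.4, 0, -0.3, 0.25, 0.15, -0.2)
  ex <- figlink:::crf_expected(ad, w0)
  analytic <- obs - ex$expected
  h <- 1e-5
  for (m in 1:8) {
    e <- numeric(8); e[m] <- h
    fd <- (ll(w0 + e) - ll(w0 - e)) / (2 * h)
    expect_equal(unname(analytic[m]), fd, tolerance = 1e-5)
  }
})

test_that("training recovers the sign of the order-preservation penalty", {
  co <- generate_corpus(8, order_preservation = 1, seed = 19)
  Ss <- lapply(co, score_article, figure_model = "pooled",
               background_model = "variable_size", lambda = 0.8)
  cr <- suppressMessages(train_crf(co, Ss, "sis"))
  expect_lt(cr$w[["EdgesCrossed"]], 0)
  expect_true(is.finite(cr$log_likelihood))
})

test_that("prediction yields per-step posteriors and membership scores", {
  co <- generate_corpus(5, seed = 37)
  Ss <- lapply(co, score_article, figure_model = "pooled",
               background_model = "variable_size", lambda = 0.8)
  cr <- suppressMessages(train_crf(co, Ss, "sis", max_iter = 50))
  pr <- predict_crf(co[[1]], cr, Ss[[1]], posteriors = TRUE)
  expect_equal(colSums(pr$state_posteriors),
               rep(1, ncol(pr$state_posteriors)), tolerance = 1e-10)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  expect_equal(dim(pr$scores), dim(Ss[[1]]))

  # w = 0 with uniform emissions: score(i,k) = #states containing i / #states
  n <- 3
  art <- co[[2]]
  cr0 <- cr; cr0$w[] <- 0
  em0 <- unit_em; em0$mu_linked <- 0
  cr0$emission <- em0
  sc <- predict_crf(art, cr0, Ss[[2]])
  n_s <- nrow(Ss[[2]])
  states <- enumerate_states(n_s, 2)
  frac <- vapply(seq_len(n_s), function(i)
    sum(vapply(states, function(A) i %in% A, TRUE)) / length(states), 1)
  expect_equal(unclass(sc)[, 1], frac, ignore_attr = TRUE)
})

test_that("a D_max=1 CRF with null weights reproduces the uniform-HMM posterior", {
  # both models share the Gaussian emissions; with w = 0 the CRF transition
  # affinities are uniform, matching a uniform-transition HMM
  z <- matrix(c(0.6, -0.2, 1.1, 0.3, -0.7, 0.9), 2, 3)
  states <- enumerate_states(2, 1)
  logE <- emission_affinities(z, unit_em, states, log = TRUE)
  str <- figlink:::crf_structure(2, 1)
  fb <- figlink:::crf_forward_backward(matrix(0, 3, 3), numeric(3), logE)
  crf_post <- exp(fb$log_alpha + fb$log_beta - fb$logZ)
  B <- emission_matrix(z, unit_em)
  hm <- structure(list(n = 2, A = matrix(1 / 3, 3, 3),
                       start = rep(1 / 3, 3), B = B),
                  class = "fl_hmm_derived")
  hmm_post <- posterior_decode(hm, drop_q0 = FALSE)
  expect_equal(crf_post, hmm_post, tolerance = 1e-10)
})
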