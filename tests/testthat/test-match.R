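test_that("rms difference matches hand computations", {
  expect_equal(rms_diff(c(.3, .2, -.4), c(.3, .2, -.4)), 0)
  expect_equal(rms_diff(c(1, 0), c(0, 1)), 1)
  expect_equal(rms_diff(c(.5, .5), c(.1, .1)), 0.4)
  expect_error(rms_diff(1:3, 1:4), class = "syndromix_shape_error")
  # rms is NOT scale invariant (unlike congruence)
  a <- c(.5, .3); b <- c(.4, .2)
  expect_false(isTRUE(all.equal(rms_diff(2 * a, b), rms_diff(a, b))))
})

test_that("congruence is cosine similarity, invariant to positive scaling", {
  expect_equal(congruence(c(.5, .5), c(.5, .5)), 1)
  expect_equal(congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(congruence(c(.8, .6), c(.6, .8)), 0.96)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(congruence(3.7 * a, b), congruence(a, b))
  expect_equal(congruence(a, 0.2 * b), congruence(a, b))
  expect_error(congruence(a, rep(0, 10)), class = "syndromix_domain_error")
})

test_that("loading_r is Pearson r with the t-transform p-value", {
  a <- c(.1, .4, -.3, .6, .2)
  lr <- loading_r(a, 2 * a + 1)
  expect_equal(lr$r, 1)
  expect_equal(loading_r(a, -a)$r, -1)
  # oracle: p = 24 pairs with r = 0.5 -> t ~ 2.71, p < 0.05
  set.seed(4)
  repeat {
    x <- rnorm(24); y <- 0.5 * x + sqrt(0.75) * rnorm(24)
    if (abs(cor(x, y) - 0.5) < 0.02) break
  }
  lr2 <- loading_r(x, y)
  r <- lr2$r
  t_oracle <- r * sqrt(22 / (1 - r^2))
  expect_equal(lr2$p_value, 2 * pt(-abs(t_oracle), 22))
  expect_lt(lr2$p_value, 0.05)
  expect_error(loading_r(a, rep(0.3, 5)), class = "syndromix_domain_error")
})

test_that("salience classification is strict at the threshold", {
  expect_equal(salience_classify(c(.5, .1, -.6)), c(1L, 0L, -1L))
  expect_equal(salience_classify(0.4), 0L)
  expect_equal(salience_classify(c(0, 0, 0)), c(0L, 0L, 0L))
})

test_that("s index matches the hand-filled 3x3 table and is symmetric", {
  a <- c(1, 1, 1, -1, 1, 0, 0)
  b <- c(1, 1, -1, -1, 1, 0, 0)
  expect_equal(s_index(a, b), 0.6)  # (3 + 1 - 1 - 0) / (3 + 1 + 1 + 0 + 0)
  expect_equal(s_index(a, a), 1)
  expect_equal(s_index(a, -a), -1)
  expect_error(s_index(c(0, 0), c(0, 0)), class = "syndromix_undefined_error")
  set.seed(6)
  for (i in 1:20) {
    x <- sample(c(-1L, 0L, 1L), 12, replace = TRUE)
    y <- sample(c(-1L, 0L, 1L), 12, replace = TRUE)
    if (all(x == 0) && all(y == 0)) next
    s1 <- s_index(x, y)
    expect_equal(s1, s_index(y, x))
    expect_gte(s1, -1); expect_lte(s1, 1)
  }
})

test_that("s significance is deterministic, extreme under perfect agreement", {
  a <- c(rep(1L, 6), rep(-1L, 2), rep(0L, 16))
  sig <- s_significance(1, a, a, n_perm = 2000, seed = 3)
  expect_lt(sig$p_value, 0.01)
  sig2 <- s_significance(1, a, a, n_perm = 2000, seed = 3)
  expect_identical(sig, sig2)
  expect_error(s_significance(1, a, a, n_perm = 100),
               class = "syndromix_domain_error")
  expect_error(s_significance(0, rep(0L, 5), c(1L, rep(0L, 4)), n_perm = 1000),
               class = "syndromix_undefined_error")
})

test_that("the 24-variable consensus regime yields the published ~0.63 threshold", {
  crit <- s_critical(n_vars = 24, pos_a = 7, neg_a = 1, pos_b = 7, neg_b = 1,
                     n_perm = 10000, seed = 11)
  expect_equal(crit, 0.63, tolerance = 0.04)
})

test_that("alignment recovers permutations, sign flips, and survives noise", {
  set.seed(9)
  a <- matrix(rnorm(24 * 3, sd = 0.4), 24, 3)
  # column swap recovered
  al <- align_components(a, a[, c(2, 3, 1)])
  expect_equal(al$pairs$component_b, c(3, 1, 2))
  expect_equal(al$pairs$cc, rep(1, 3), tolerance = 1e-12)
  # sign flips detected and undone
  al2 <- align_components(a, -a)
  expect_true(all(al2$pairs$flipped))
  expect_equal(al2$b_aligned, a, ignore_attr = TRUE)
  # small perturbation: identity pairing, high congruence
  al3 <- align_components(a, a + matrix(rnorm(72, sd = 0.05), 24, 3))
  expect_equal(al3$pairs$component_b, 1:3)
  expect_true(all(al3$pairs$cc > 0.95))
  # unequal component counts: surplus reported as unmatched
  al4 <- align_components(a, a[, 1:2])
  expect_equal(nrow(al4$pairs), 2)
  expect_length(al4$unmatched_a, 1)
  expect_error(align_components(a, a[1:10, ]), class = "syndromix_shape_error")
})

test_that("match_report: self-match is perfect, random loadings fail consensus", {
  set.seed(10)
  a <- matrix(rnorm(24 * 3, sd = 0.45), 24, 3)
  self <- match_report(a, a, n_perm = 1500, seed = 1)
  expect_equal(self$rms, rep(0, 3))
  expect_equal(self$cc, rep(1, 3))
  expect_equal(self$r, rep(1, 3))
  expect_equal(self$s, rep(1, 3))
  expect_true(all(self$consensus_pass))

  fails <- sapply(1:5, function(i) {
    b <- matrix(rnorm(24 * 3, sd = 0.45), 24, 3)
    any(match_report(a, b, n_perm = 1500, seed = i)$consensus_pass)
  })
  expect_true(sum(fails) <= 1)  # overwhelmingly no consensus vs independent noise
})

test_that("match_report is invariant to column permutation and sign flips of b", {
  set.seed(12)
  a <- matrix(rnorm(24 * 3, sd = 0.45), 24, 3)
  b <- a + matrix(rnorm(72, sd = 0.1), 24, 3)
  base <- match_report(a, b, n_perm = 1500, seed = 2)
  scrambled <- b[, c(3, 1, 2)] %*% diag(c(-1, 1, -1))
  rep2 <- match_report(a, scrambled, n_perm = 1500, seed = 2)
  ord <- order(rep2$component_a)
  for (col in c("rms", "cc", "r", "s")) {
    expect_equal(rep2[[col]][ord], base[[col]], tolerance = 1e-12)
  }
})

test_that("permutation p-values are valid (super-uniform under their own null)", {
  # under the label-permutation null itself, rejection at .05 stays near .05
  set.seed(20)
  n_rep <- 400
  a <- c(rep(1L, 7), rep(-1L, 2), rep(0L, 15))
  b0 <- c(rep(1L, 6), rep(-1L, 3), rep(0L, 15))
  rejections <- 0
  for (i in seq_len(n_rep)) {
    b <- sample(b0)
    s <- s_index(a, b)
    p <- s_significance(s, a, b, n_perm = 1000, seed = i)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.07)
})
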