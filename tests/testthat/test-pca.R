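test_that("two-variable extraction matches the closed form", {
  r <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  m <- pca_extract(r)
  expect_equal(m$eigenvalues, c(1.6, 0.4))
  expect_equal(unname(m$loadings[, 1]), c(sqrt(0.8), sqrt(0.8)), tolerance = 1e-6)
  expect_equal(sum(m$eigenvalues), 2)
  expect_equal(sum(m$variance_proportion), 1)
})

test_that("identity correlation gives unit eigenvalues and orthonormal loadings", {
  m <- pca_extract(diag(5))
  expect_equal(m$eigenvalues, rep(1, 5))
  expect_equal(crossprod(m$loadings), diag(5), ignore_attr = TRUE)
})

test_that("full extraction reconstructs R and loadings equal variable-score correlations", {
  set.seed(42)
  for (i in 1:5) {
    p <- sample(5:8, 1)
    x <- matrix(rnorm(300 * p), 300, p)
    x[, 1] <- x[, 2] * 0.7 + x[, 1] * 0.5  # some structure
    r <- cor(x)
    m <- pca_extract(r)
    expect_lt(max(abs(tcrossprod(m$loadings) - r)), 1e-8)
    # oracle: loading(j, k) = cor(variable j, score k)
    sc <- compute_scores(scale(x), m)
    expect_lt(max(abs(cor(scale(x), sc) - m$loadings)), 1e-6)
    expect_lt(max(abs(colMeans(sc))), 1e-10)
    expect_equal(unname(apply(sc, 2, sd)), rep(1, p), tolerance = 1e-10)
  }
})

test_that("extraction agrees with a brute-force eigendecomposition oracle", {
  set.seed(7)
  for (i in 1:5) {
    r <- random_cor(5)
    m <- pca_extract(r)
    e <- eigen((r + t(r)) / 2, symmetric = TRUE)  # independent route
    expect_equal(m$eigenvalues, e$values, tolerance = 1e-8)
    for (k in 1:5) {
      oracle <- e$vectors[, k] * sqrt(e$values[k])
      expect_equal(abs(unname(m$loadings[, k])), abs(oracle), tolerance = 1e-8)
    }
  }
})

test_that("sign orientation is deterministic", {
  set.seed(3)
  r <- random_cor(6)
  m1 <- pca_extract(r)
  m2 <- pca_extract(r)
  expect_identical(m1$loadings, m2$loadings)
  # largest-|loading| entry of each component is positive
  for (k in 1:6) {
    v <- m1$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("non-symmetric input is refused, communalities bounded", {
  r <- random_cor(4)
  r2 <- r; r2[1, 2] <- r2[1, 2] + 0.01
  expect_error(pca_extract(r2), class = "syndromix_domain_error")
  m <- pca_extract(r, 2)
  expect_true(all(m$communalities >= 0 & m$communalities <= 1 + 1e-12))
})

test_that("Kaiser rule counts eigenvalues strictly above 1", {
  expect_equal(retain_kaiser(c(2.5, 1.2, 0.8, 0.5)), 2)
  expect_equal(retain_kaiser(rep(1, 6)), 0)  # strict inequality
  expect_equal(retain_kaiser(c(8.3, 5.0, 1.8, 1.1, 1.05, 0.9, 0.5)), 5)
})

test_that("scree elbow is the maximum second difference with smallest-index ties", {
  # hand computation: second differences 0.5, 1.1, 1.3, 0.05 -> elbow at 4
  expect_equal(retain_scree(c(8, 5, 2.5, 1.1, 1.0, 0.95)), 3)
  # hand computation: 1.9, -0.25, 0.35 -> elbow at 2
  expect_equal(retain_scree(c(3, 1, 0.9, 0.55, 0.55)), 1)
  # linear decay ties everywhere -> smallest qualifying index
  expect_equal(retain_scree(c(4, 3, 2, 1)), 1)
  expect_error(retain_scree(c(2, 1, 0.5)), class = "syndromix_rule_error")
})

test_that("over-determination counts leading components with enough salients", {
  l <- cbind(c(rep(0.6, 5), rep(0.1, 5)), c(0.5, 0.5, rep(0.05, 8)))
  expect_equal(retain_overdetermination(l), 1)
  expect_equal(retain_overdetermination(matrix(0.2, 6, 3)), 0)
  # salience is strict: exactly 0.4 does not count
  l2 <- matrix(0.4, 6, 1)
  expect_equal(retain_overdetermination(l2), 0)
})

test_that("consensus retention is the min-style combination of the three rules", {
  # rules (kaiser, scree, overdet) = (5, 3, 3) -> 3, mirrored by construction
  ev <- c(8.3, 5.0, 1.8, 1.1, 1.05, rep(0.6, 19))
  load <- matrix(0, 24, 24)
  load[1:5, 1] <- 0.7; load[6:10, 2] <- 0.7; load[11:14, 3] <- 0.7
  rd <- retain_consensus(ev, load)
  expect_equal(rd$kaiser, 5)
  expect_equal(rd$overdetermination, 3)
  expect_equal(rd$consensus, min(rd$kaiser, rd$scree, rd$overdetermination))
  expect_lte(rd$consensus, min(rd$kaiser, rd$overdetermination))
  # identity correlation: nothing retained
  m <- pca_extract(diag(8))
  rd0 <- retain_consensus(m$eigenvalues, m$loadings)
  expect_equal(rd0$consensus, 0)
})

test_that("components are named by strict salient loadings, sorted by magnitude", {
  load <- matrix(c(0.9, 0.5, 0.1, -0.45, 0.4, 0.2), 6, 1,
                 dimnames = list(letters[1:6], "PC1"))
  m <- structure(list(loadings = load), class = "pc_model")
  nm <- name_component(m, 1)
  expect_equal(nm$variable, c("a", "b", "d"))  # 0.4 excluded (strict)
  expect_equal(nm$sign, c("+", "+", "-"))
  m0 <- structure(list(loadings = load * 0.1), class = "pc_model")
  expect_warning(nm0 <- name_component(m0, 1), "no loading")
  expect_equal(nrow(nm0), 0)
})

test_that("varimax preserves communalities and does not decrease the criterion", {
  vm_crit <- function(l) {
    # standard varimax simplicity criterion
    sum(apply(l^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
  }
  set.seed(5)
  for (i in 1:3) {
    l <- matrix(rnorm(30, sd = 0.4), 10, 3)
    m <- structure(list(loadings = l, rotation = "none"), class = "pc_model")
    r <- rotate_varimax(m)
    expect_equal(rowSums(r$loadings^2), rowSums(l^2), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_gte(vm_crit(r$loadings), vm_crit(l) - 1e-10)
  }
  # block-diagonal simple structure is a fixed point up to sign/permutation
  l <- rbind(cbind(rep(0.8, 5), 0), cbind(0, rep(0.7, 5)))
  m <- structure(list(loadings = l, rotation = "none"), class = "pc_model")
  r <- rotate_varimax(m)
  al <- align_components(l, r$loadings)
  expect_equal(al$pairs$cc, c(1, 1), tolerance = 1e-6)
})

test_that("promax recovers factor correlations and reduces to identity at K=1", {
  # orthogonal generating structure: factor correlations near zero
  set.seed(8)
  l <- rbind(cbind(runif(8, .5, .8), 0, 0), cbind(0, runif(8, .5, .8), 0),
             cbind(0, 0, runif(8, .5, .8)))
  x <- matrix(rnorm(3000 * 3), 3000, 3) %*% t(l) +
    matrix(rnorm(3000 * 24), 3000, 24) %*% diag(sqrt(1 - rowSums(l^2)))
  m <- pca_extract(cor(x), 3)
  pm <- rotate_promax(m)
  off <- pm$factor_correlations[upper.tri(pm$factor_correlations)]
  expect_lt(max(abs(off)), 0.15)

  # correlated factors (r = 0.5) recovered within 0.15
  phi <- matrix(0.5, 3, 3); diag(phi) <- 1
  f <- matrix(rnorm(3000 * 3), 3000, 3) %*% chol(phi)
  x2 <- f %*% t(l) + matrix(rnorm(3000 * 24), 3000, 24) %*% diag(sqrt(1 - rowSums(l^2)))
  pm2 <- rotate_promax(pca_extract(cor(x2), 3))
  off2 <- pm2$factor_correlations[upper.tri(pm2$factor_correlations)]
  expect_true(all(abs(off2 - 0.5) < 0.15))

  m1 <- pca_extract(cor(x), 1)
  expect_equal(rotate_promax(m1)$loadings, m1$loadings)
})

test_that("correlation_matrix validates input and pools under missingness", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- correlation_matrix(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_error(correlation_matrix(cbind(a = rep(1, 5), b = rnorm(5))),
               class = "syndromix_domain_error")
  set.seed(2)
  xg <- matrix(rnorm(600 * 4), 600, 4)
  expect_lt(max(abs(correlation_matrix(xg) - diag(4))), 0.15)
})
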