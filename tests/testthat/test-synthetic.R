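test_that("generation is a deterministic function of the configuration", {
  d1 <- syn_generate(syn_config(seed = 21))
  d2 <- syn_generate(syn_config(seed = 21))
  expect_identical(d1$outcomes, d2$outcomes)
  expect_identical(d1$truth$factor_scores, d2$truth$factor_scores)
  d3 <- syn_generate(syn_config(seed = 22))
  expect_false(identical(d1$truth$factor_scores, d3$truth$factor_scores))
})

test_that("configuration invariants are enforced", {
  tpl <- syn_loading_template()
  expect_true(all(tpl$f1^2 + tpl$f2^2 + tpl$f3^2 < 1))
  tpl_bad <- tpl
  tpl_bad$f1[1] <- 0.99; tpl_bad$f2[1] <- 0.5
  expect_error(syn_config(loading_template = tpl_bad), "grooming_left",
               class = "syndromix_config_error")
  expect_error(syn_config(missing_rate = 0.5), class = "syndromix_config_error")
  # every factor has at least 3 salient variables (over-determination reachable)
  lam <- as.matrix(tpl[, c("f1", "f2", "f3")])
  expect_true(all(colSums(abs(lam) > 0.4) >= 3))
})

test_that("sample correlations converge to the implied population matrix", {
  cfg <- syn_config(seed = 30)
  gd <- cfg$group_design
  gd$n <- round(gd$n * 1000 / sum(gd$n))
  big <- syn_generate(syn_config(group_design = gd, missing_rate = 0,
                                 group_shift_sd = c(0, 0, 0), seed = 30))
  r <- cor(matrix_values(big$matrix))
  expect_lt(max(abs(r - big$truth$population_correlation)), 0.1)
})

test_that("the noiseless limit shows exactly three dominant eigenvalues", {
  tpl <- syn_loading_template()
  # push uniqueness toward zero by scaling loadings near the communality bound
  lam <- as.matrix(tpl[, c("f1", "f2", "f3")])
  scl <- sqrt(0.995 / rowSums(lam^2))
  tpl[, c("f1", "f2", "f3")] <- lam * scl
  gd <- syn_group_design(); gd$n <- gd$n * 4
  dat <- syn_generate(syn_config(group_design = gd, loading_template = tpl,
                                 missing_rate = 0, seed = 31))
  ev <- eigen(cor(matrix_values(dat$matrix)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[3] / ev[4], 20)
})

test_that("group-mean shifts leave loading recovery intact", {
  dat <- syn_generate(syn_config(missing_rate = 0, seed = 32))
  x <- matrix_values(dat$matrix)
  # center within group, then extract: patterns should match the template
  xc <- x
  for (g in unique(dat$truth$group)) {
    idx <- dat$truth$group == g
    xc[idx, ] <- scale(x[idx, ], scale = FALSE)
  }
  m <- pca_extract(cor(xc), 3)
  al <- align_components(dat$truth$loadings, m$loadings)
  expect_gt(min(al$pairs$cc), 0.9)
  expect_gt(mean(al$pairs$cc), 0.95)
})

test_that("null data mostly retain zero components by consensus", {
  cons <- sapply(1:15, function(s) {
    x <- syn_null(400, 24, seed = s)
    f <- pca_extract(correlation_matrix(x), "all")
    retain_consensus(f$eigenvalues, f$loadings)$consensus
  })
  expect_gte(sum(cons == 0), 8)  # majority behaviour; chance salience allows a few 1s
})

test_that("device split shares the template and degenerates to a perfect match without noise", {
  cfg <- syn_config(seed = 33, missing_rate = 0)
  sp <- syn_device_split(cfg)
  expect_setequal(unique(sp$nyu$matrix$device), "NYU")
  expect_setequal(unique(sp$ih$matrix$device), "IH")
  expect_equal(nrow(sp$nyu$matrix), 52)
  expect_equal(nrow(sp$ih$matrix), 98)
  expect_identical(sp$nyu$truth$loadings, sp$ih$truth$loadings)
  # identical copies of one dataset -> perfect match end to end
  m <- syndromic_pca(sp$nyu$matrix, seed = 1)
  rep <- match_report(m$loadings, m$loadings, n_perm = 1500, seed = 1)
  expect_true(all(rep$consensus_pass))
})

test_that("perturbed split zeroes the targeted loadings in one half only", {
  sp <- syn_device_split(syn_config(seed = 34),
                         perturb = c("print_area_fl_r", "stride_length_fl_r"))
  expect_equal(unname(sp$ih$truth$loadings["print_area_fl_r", ]), c(0, 0, 0))
  expect_false(all(sp$nyu$truth$loadings["print_area_fl_r", ] == 0))
})

test_that("null scenario has no structure: top eigenvalue shrinks toward 1 with n", {
  ev_top <- sapply(c(120, 1200), function(n) {
    eigen(cor(matrix_values(syn_null(n, 24, seed = 35))),
          symmetric = TRUE, only.values = TRUE)$values[1]
  })
  expect_lt(ev_top[2], ev_top[1])
  expect_lt(ev_top[2], 1.5)
})
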