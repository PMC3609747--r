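test_that("subsetting to all variables reproduces the full extraction", {
  dat <- syn_generate(syn_config(missing_rate = 0, seed = 41))
  res <- subset_variable_pca(dat$matrix,
                             c("behavioral", "histological", "health"),
                             seed = 1, n_perm = 1500)
  expect_true(all(res$report$cc > 0.999))
  expect_true(all(res$report$rms < 1e-6))
})

test_that("histology-only extraction reproduces the tissue-sparing component", {
  dat <- syn_generate(syn_config(missing_rate = 0, seed = 42))
  res <- subset_variable_pca(dat$matrix, "histological", seed = 1, n_perm = 1500)
  # a single histology component that is congruent with full-battery PC1
  expect_equal(ncol(res$subset$loadings), 1)
  rep <- res$report
  expect_equal(rep$component_a, 1)
  expect_gt(rep$cc, 0.95)
  expect_true(rep$pass_rms && rep$pass_cc && rep$pass_r)
  expect_equal(rep$s, 1)
  # with 6 variables all salient in both patterns, the permutation null of s
  # is degenerate: its attainable p-value floor (1/6) sits above 0.05
  expect_gte(rep$p_s, 1 / 6 - 0.05)
})

test_that("behaviour-only extraction reports the PC1/PC2 order swap", {
  dat <- syn_generate(syn_config(missing_rate = 0, seed = 42))
  res <- subset_variable_pca(dat$matrix, c("behavioral", "health"),
                             seed = 1, n_perm = 1500)
  rep <- res$report
  # histology dominates factor 1; dropping it flips the variance ordering
  expect_equal(rep$component_b[rep$component_a == 1], 2)
  expect_equal(rep$component_b[rep$component_a == 2], 1)
  expect_true(all(rep$cc > 0.75))
  expect_error(subset_variable_pca(dat$matrix, "health"),
               class = "syndromix_rule_error")
})

test_that("device split replicates PC1 and builds a nonempty consensus", {
  sp <- syn_device_split(syn_config(seed = 43))
  vi <- var_info(sp$nyu$matrix)
  both <- dplyr::bind_rows(tibble::as_tibble(sp$nyu$matrix),
                           tibble::as_tibble(sp$ih$matrix))
  both <- syndromix:::new_analysis_matrix(both, vi)
  cs <- split_case_pca(both, "device", seed = 2, n_perm = 1500)
  rep <- cs$report
  pc1 <- rep[rep$component_a == 1, ]
  # the primary pattern replicates: high congruence, significant r and s
  expect_gt(pc1$cc, 0.9)
  expect_true(pc1$pass_r)
  expect_true(pc1$pass_s)
  expect_gt(sum(!is.na(cs$consensus$consensus)), 0)
  # every consensus entry was salient in both halves
  kept <- cs$consensus[!is.na(cs$consensus$consensus), ]
  expect_true(all(abs(kept$loading_a) > 0.4 & abs(kept$loading_b) > 0.4))
})

test_that("a pure-noise half yields an empty consensus", {
  dat <- syn_generate(syn_config(seed = 44, missing_rate = 0))
  noise <- syn_null(100, 24, seed = 45)
  # same variable names so the halves are comparable
  vi <- var_info(dat$matrix)
  noise_tbl <- tibble::as_tibble(noise)
  names(noise_tbl)[-(1:4)] <- vi$variable
  noise_tbl$device <- "IH"
  both <- dplyr::bind_rows(
    tibble::as_tibble(dat$matrix)[dat$matrix$device == "NYU", ],
    noise_tbl
  )
  both <- syndromix:::new_analysis_matrix(both, vi)
  cs <- split_case_pca(both, "device", seed = 3, n_perm = 1500)
  expect_false(any(cs$report$consensus_pass))
  # chance salience in a noise extraction can leave a stray cell or two,
  # but nothing resembling the structured half's consensus
  expect_lte(sum(!is.na(cs$consensus$consensus)), 3)
})

test_that("consensus_pattern applies the both-salient rule and is symmetric", {
  a <- matrix(c(0.6, 0.5, 0.3, 0.45), 4, 1, dimnames = list(letters[1:4], "PC1"))
  b <- matrix(c(0.3, 0.7, 0.6, -0.45), 4, 1, dimnames = list(letters[1:4], "PC1"))
  cp <- consensus_pattern(a, b)
  expect_true(is.na(cp$consensus[cp$variable == "a"]))  # 0.6 vs 0.3 -> absent
  expect_equal(cp$consensus[cp$variable == "b"], 0.6)   # (0.5 + 0.7) / 2
  expect_true(is.na(cp$consensus[cp$variable == "c"]))
  # sign-discordant salient pair flagged, never averaged
  expect_true(cp$discordant[cp$variable == "d"])
  expect_true(is.na(cp$consensus[cp$variable == "d"]))
  cp_ba <- consensus_pattern(b, a)
  expect_equal(cp_ba$consensus, cp$consensus)
  expect_equal(cp_ba$discordant, cp$discordant)
  # a vs a: consensus equals a restricted to its salient entries
  cp_aa <- consensus_pattern(a, a)
  expect_equal(cp_aa$consensus[!is.na(cp_aa$consensus)],
               a[abs(a) > 0.4, 1], ignore_attr = TRUE)
})

test_that("equalized-n subsampling is deterministic and errors on small groups", {
  dat <- syn_generate(syn_config(seed = 46))
  expect_error(subsample_equalized(dat$matrix, n_per_group = 9, iterations = 2),
               "sham_ih", class = "syndromix_integrity_error")
  r1 <- suppressWarnings(
    subsample_equalized(dat$matrix, n_per_group = 9, iterations = 3,
                        seed = 5, undersized = "drop", n_perm = 1200)
  )
  r2 <- suppressWarnings(
    subsample_equalized(dat$matrix, n_per_group = 9, iterations = 3,
                        seed = 5, undersized = "drop", n_perm = 1200)
  )
  expect_identical(r1$summary, r2$summary)
  expect_false("sham_ih" %in% r1$groups_used)
  # inputs are left unmodified (pure function over the data)
  before <- matrix_values(dat$matrix)
  invisible(suppressWarnings(
    subsample_equalized(dat$matrix, n_per_group = 6, iterations = 2,
                        seed = 1, n_perm = 1200)
  ))
  expect_identical(matrix_values(dat$matrix), before)
})

test_that("subsampling with whole equal groups degenerates to the self-match", {
  gd <- syn_group_design()[c(2, 3, 5), ]
  gd$n <- c(12, 12, 12)
  dat <- syn_generate(syn_config(group_design = gd, missing_rate = 0, seed = 47))
  res <- subsample_equalized(dat$matrix, n_per_group = 12, iterations = 2,
                             seed = 6, n_perm = 1200)
  expect_true(all(abs(res$summary$cc_mean - 1) < 1e-10))
  expect_true(all(res$summary$rms_mean < 1e-10))
})
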