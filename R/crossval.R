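#' Variable-subset extraction and comparison with the full extraction
#'
#' Re-runs the PCA on a subset of variable classes only (e.g. histology
#' alone, or behaviour alone) and compares the resulting component patterns
#' to the full-battery extraction, restricted to the shared variables. High
#' construct validity shows as consistent loading patterns however the
#' battery is subsetted; order swaps between components (the subset's PC1
#' matching the full PC2, say) are reported by the alignment.
#'
#' @param x An `analysis_matrix`.
#' @param classes Character subset of `c("behavioral", "histological",
#'   "health")`.
#' @param threshold,min_salient,m,seed Passed through to [syndromic_pca()]
#'   and [match_report()].
#' @param n_perm Permutations for the s null.
#' @return A list: `full` and `subset` (`pc_model`s), `report`
#'   (a `match_report` on the shared variables).
#' @export
subset_variable_pca <- function(x, classes, threshold = 0.4, min_salient = 3,
                                m = 5, seed = 1, n_perm = 2000) {
  vi <- var_info(x)
  keep <- vi$variable[vi$class %in% classes]
  if (length(keep) < 3) {
    abort("variable subset must contain at least 3 variables",
          class = "syndromix_rule_error")
  }
  full <- syndromic_pca(x, threshold = threshold, min_salient = min_salient,
                        m = m, seed = seed)
  sub_x <- x[, c(id_columns, keep)]
  sub_x <- new_analysis_matrix(sub_x, vi[vi$class %in% classes, ])
  subset_fit <- syndromic_pca(sub_x, threshold = threshold, min_salient = min_salient,
                              m = m, seed = seed)
  report <- match_report(full$loadings[keep, , drop = FALSE],
                         subset_fit$loadings,
                         threshold = threshold, n_perm = n_perm, seed = seed)
  list(full = full, subset = subset_fit, report = report)
}

#' Case-split extraction, pairwise comparison and consensus pattern
#'
#' Splits the subjects into two subpopulations (by device, by default),
#' extracts components independently in each, aligns and compares the
#' loading patterns, and builds the consensus pattern of loadings salient in
#' both halves. Patterns that survive this case cross-validation generalize
#' across subject populations.
#'
#' @param x An `analysis_matrix`.
#' @param split Either a column name of `x` (default `"device"`) or a vector
#'   with one label per subject defining two subsets.
#' @param k `"parent"` (default): each subset extracts the number of
#'   components retained by the consensus rule on the pooled matrix (the
#'   subsets answer "do the pooled components replicate?");
#'   `"consensus"`: each subset applies the retention rules to itself;
#'   or an integer.
#' @param threshold,min_salient,m,seed,n_perm As in [subset_variable_pca()].
#' @return A list: `models` (named list of `pc_model`s), `report`
#'   (a `match_report`), `consensus` (tibble from [consensus_pattern()]).
#' @export
split_case_pca <- function(x, split = "device", k = "parent", threshold = 0.4,
                           min_salient = 3, m = 5, seed = 1, n_perm = 2000) {
  labels <- if (length(split) == 1 && is.character(split) && split %in% names(x)) {
    x[[split]]
  } else {
    split
  }
  stopifnot(length(labels) == nrow(x))
  lev <- unique(labels)
  if (length(lev) != 2) {
    abort("split must define exactly two subsets", class = "syndromix_domain_error")
  }
  vi <- var_info(x)
  p <- nrow(vi)
  seeds <- derive_seeds(seed, 3)
  k_sub <- if (identical(k, "parent")) {
    parent <- syndromic_pca(x, threshold = threshold, min_salient = min_salient,
                            m = m, seed = seeds[3])
    max(parent$retention$consensus, 1L)
  } else {
    k
  }
  models <- purrr::map(seq_along(lev), function(i) {
    xi <- x[labels == lev[i], ]
    xi <- new_analysis_matrix(xi, vi)
    if (nrow(xi) < 3 * p / 2) {
      warn(sprintf("subset '%s' has only %d subjects for %d variables",
                   lev[i], nrow(xi), p))
    }
    syndromic_pca(xi, k = k_sub, threshold = threshold, min_salient = min_salient,
                  m = m, seed = seeds[i])
  })
  names(models) <- lev
  report <- match_report(models[[1]]$loadings, models[[2]]$loadings,
                         threshold = threshold, n_perm = n_perm, seed = seed)
  al <- attr(report, "alignment")
  cons <- consensus_pattern(models[[1]]$loadings[, report$component_a, drop = FALSE],
                            al$b_aligned, threshold = threshold)
  list(models = models, report = report, consensus = cons)
}

#' Consensus pattern of two aligned loading matrices
#'
#' Keeps, per variable and component, only loadings salient (strictly above
#' the threshold in absolute value) in both matrices, and averages them.
#' Salient pairs with discordant signs are not averaged -- averaging
#' opposite signs would fabricate a pattern -- but flagged in the
#' `discordant` column.
#'
#' @param a,b Aligned loading matrices (same variables, paired columns).
#' @param threshold Salience cutoff (default 0.4).
#' @return A tibble with columns `variable`, `component`, `loading_a`,
#'   `loading_b`, `consensus` (`NA` unless salient in both with matching
#'   sign), `discordant`.
#' @export
consensus_pattern <- function(a, b, threshold = 0.4) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(dim(a) == dim(b))
  vn <- rownames(a)
  if (is.null(vn)) vn <- paste0("V", seq_len(nrow(a)))
  cn <- colnames(a)
  if (is.null(cn)) cn <- paste0("PC", seq_len(ncol(a)))
  out <- tidyr::crossing(component = cn, variable = vn)
  out <- out[order(match(out$component, cn), match(out$variable, vn)), ]
  ia <- as.vector(a[cbind(match(out$variable, vn), match(out$component, cn))])
  ib <- as.vector(b[cbind(match(out$variable, vn), match(out$component, cn))])
  both_salient <- abs(ia) > threshold & abs(ib) > threshold
  concordant <- sign(ia) == sign(ib)
  out$loading_a <- ia
  out$loading_b <- ib
  out$consensus <- ifelse(both_salient & concordant, (ia + ib) / 2, NA_real_)
  out$discordant <- both_salient & !concordant
  tibble::as_tibble(out)
}

#' Equalized-n subsampling stability of component patterns
#'
#' Pooled designs are unbalanced; this checks that the component patterns do
#' not hinge on the large groups. Per iteration, `n_per_group` subjects are
#' drawn without replacement from every group, components are extracted from
#' the subsample, aligned to the full-data loadings, and the four matching
#' statistics computed; statistics are averaged across iterations.
#'
#' @param x An `analysis_matrix`.
#' @param n_per_group Subjects drawn per group (default 9).
#' @param iterations Number of subsampling iterations (default 10).
#' @param seed Integer seed (governs the whole iteration sequence).
#' @param undersized `"error"` (default): a group smaller than `n_per_group`
#'   is an integrity error naming the group; `"drop"`: such groups are
#'   excluded from the subsampling.
#' @param threshold,min_salient,m,n_perm As in [subset_variable_pca()].
#' @return A list: `summary` (tibble of per-component means and SDs of the
#'   four statistics), `iterations` (per-iteration tibble, kept for audit),
#'   `full` (the full-data `pc_model`).
#' @export
subsample_equalized <- function(x, n_per_group = 9, iterations = 10, seed = 1,
                                undersized = c("error", "drop"),
                                threshold = 0.4, min_salient = 3, m = 5,
                                n_perm = 2000) {
  undersized <- match.arg(undersized)
  counts <- table(x$group)
  small <- names(counts)[counts < n_per_group]
  if (length(small) > 0) {
    if (undersized == "error") {
      abort(paste0("group(s) smaller than n_per_group = ", n_per_group, ": ",
                   paste(small, collapse = ", ")),
            class = "syndromix_integrity_error")
    }
    warn(paste0("dropping undersized group(s): ", paste(small, collapse = ", ")))
  }
  keep_groups <- setdiff(names(counts), small)
  vi <- var_info(x)
  full <- syndromic_pca(x, threshold = threshold, min_salient = min_salient,
                        m = m, seed = seed)
  k_full <- ncol(full$loadings)
  seeds <- derive_seeds(seed, iterations)
  per_iter <- purrr::map(seq_len(iterations), function(it) {
    idx <- with_seed(seeds[it], {
      unlist(purrr::map(keep_groups, function(g) {
        sample(which(x$group == g), n_per_group)
      }))
    })
    xi <- new_analysis_matrix(x[sort(idx), ], vi)
    fit <- syndromic_pca(xi, k = k_full, threshold = threshold,
                         min_salient = min_salient, m = m, seed = seeds[it])
    rep <- match_report(full$loadings, fit$loadings, threshold = threshold,
                        n_perm = n_perm, seed = seeds[it])
    rep$iteration <- it
    rep
  })
  per_iter <- dplyr::bind_rows(lapply(per_iter, function(r) {
    tibble::as_tibble(r[, c("iteration", "component_a", "component_b",
                            "rms", "cc", "r", "s")])
  }))
  summary <- dplyr::summarise(
    dplyr::group_by(per_iter, component = .data$component_a),
    dplyr::across(c("rms", "cc", "r", "s"),
                  list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
    .groups = "drop"
  )
  list(summary = summary, iterations = per_iter, full = full,
       n_per_group = n_per_group, groups_used = keep_groups, seed = seed)
}
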