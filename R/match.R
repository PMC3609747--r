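#' @title Factor pattern-matching statistics
#' @description
#' Four complementary statistics quantify whether a component loading
#' pattern replicates across two extractions: the root-mean-square
#' difference (RMS, 0 = identical), the coefficient of congruence (CC,
#' cosine similarity, 1 = identical shape and sign), the Pearson correlation
#' across loading entries (r, with a t-based p-value), and the salient
#' variable similarity index (s, a sign-agreement index over the variables
#' salient in either pattern, with a Monte-Carlo permutation p-value).
#' Consensus across all four is the replication criterion.
#' @name pattern-matching
NULL

#' Root-mean-square difference between two loading vectors
#'
#' @param a,b Equal-length loading vectors (length >= 2).
#' @return `sqrt(mean((a - b)^2))`; 0 indicates identical patterns.
#' @export
#' @examples
#' rms_diff(c(.5, .5), c(.1, .1))  # 0.4
rms_diff <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("vectors must have equal length >= 2", class = "syndromix_shape_error")
  }
  sqrt(mean((a - b)^2))
}

#' Coefficient of congruence between two loading vectors
#'
#' Cosine similarity: `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`. Invariant to
#' positive rescaling of either argument; values near 1 indicate agreement
#' of both sign and relative magnitude.
#'
#' @param a,b Equal-length loading vectors, each with at least one nonzero
#'   entry.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' congruence(c(.8, .6), c(.6, .8))  # 0.96
congruence <- function(a, b) {
  if (length(a) != length(b)) {
    abort("vectors must have equal length", class = "syndromix_shape_error")
  }
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) {
    abort("congruence undefined for a zero vector", class = "syndromix_domain_error")
  }
  sum(a * b) / sqrt(na2 * nb2)
}

#' Pearson correlation between two loading vectors
#'
#' Correlation across the p loading entries, with the two-sided p-value from
#' the t transform on p - 2 degrees of freedom.
#'
#' @param a,b Equal-length loading vectors (length >= 3, nonzero variance).
#' @return A list with elements `r` and `p_value`.
#' @export
loading_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("vectors must have equal length >= 3", class = "syndromix_shape_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("loading_r undefined for zero-variance vector", class = "syndromix_domain_error")
  }
  r <- cor(a, b)
  df <- length(a) - 2
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p_value = p)
}

#' Classify loadings as salient-positive, hyperplane, or salient-negative
#'
#' @param v Loading vector.
#' @param threshold Salience cutoff (strict; default 0.4).
#' @return Integer vector in `{-1, 0, +1}`.
#' @export
#' @examples
#' salience_classify(c(.5, .1, -.6))  # 1 0 -1
#' salience_classify(0.4)             # 0  (strict inequality)
salience_classify <- function(v, threshold = 0.4) {
  stopifnot(threshold > 0)
  out <- integer(length(v))
  out[v > threshold] <- 1L
  out[v < -threshold] <- -1L
  out
}

#' Salient variable similarity index
#'
#' Cross-classifies the variables of two salience patterns into a 3 x 3
#' table (positive-salient / hyperplane / negative-salient) and scores sign
#' agreement among salient variables, counting salient-vs-hyperplane
#' disagreements at half weight and ignoring the hyperplane-hyperplane cell:
#' `s = (f[+,+] + f[-,-] - f[+,-] - f[-,+]) /
#'      (f[+,+] + f[-,-] + f[+,-] + f[-,+] +
#'       (f[+,0] + f[0,+] + f[-,0] + f[0,-]) / 2)`.
#'
#' @param a,b Salience vectors (entries in `{-1, 0, 1}`, equal length), as
#'   produced by [salience_classify()].
#' @return A number in `[-1, 1]`; 1 = identical salience patterns, -1 =
#'   exact sign reversal.
#' @export
#' @examples
#' a <- c(1, 1, 1, -1, 1, 0, 0)
#' b <- c(1, 1, -1, -1, 1, 0, 0)
#' s_index(a, b)  # 0.6
s_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("patterns must have equal length", class = "syndromix_shape_error")
  }
  stopifnot(all(a %in% c(-1L, 0L, 1L)), all(b %in% c(-1L, 0L, 1L)))
  fpp <- sum(a == 1 & b == 1)
  fmm <- sum(a == -1 & b == -1)
  fpm <- sum(a == 1 & b == -1)
  fmp <- sum(a == -1 & b == 1)
  fh <- sum(a != 0 & b == 0) + sum(a == 0 & b != 0)
  denom <- fpp + fmm + fpm + fmp + fh / 2
  if (denom == 0) {
    abort("s undefined: both patterns entirely hyperplane",
          class = "syndromix_undefined_error")
  }
  (fpp + fmm - fpm - fmp) / denom
}

# vectorized s over a matrix of permuted b-patterns (columns)
s_index_many <- function(a, bm) {
  fpp <- colSums((a == 1) & (bm == 1))
  fmm <- colSums((a == -1) & (bm == -1))
  fpm <- colSums((a == 1) & (bm == -1))
  fmp <- colSums((a == -1) & (bm == 1))
  fh <- colSums((a != 0) & (bm == 0)) + colSums((a == 0) & (bm != 0))
  (fpp + fmm - fpm - fmp) / (fpp + fmm + fpm + fmp + fh / 2)
}

#' Monte-Carlo significance of the salient variable similarity index
#'
#' Builds the null distribution of s for two patterns with the observed
#' marginal salience counts by randomly permuting one pattern's variable
#' labels, per the factor-matching null: which variables are salient is
#' random, how many (and their signs) is fixed. Reports
#' `p = (1 + #(s_null >= s_obs)) / (1 + n_perm)` and the attained
#' significance threshold: the smallest achievable s whose permutation
#' p-value is at most `alpha`. (The null is discrete, so this threshold --
#' not an interpolated percentile -- is the value an observed s must reach
#' to be called significant.)
#'
#' @param s_obs Observed s.
#' @param a,b The two salience vectors.
#' @param n_perm Number of permutations (>= 1000; default 10000).
#' @param seed Integer seed (deterministic given seed).
#' @param alpha Significance level for the reported critical value.
#' @return A list: `p_value`, `critical_value`, `n_perm`.
#' @export
s_significance <- function(s_obs, a, b, n_perm = 10000, seed = 1, alpha = 0.05) {
  if (n_perm < 1000) {
    abort("n_perm must be at least 1000", class = "syndromix_domain_error")
  }
  if (all(a == 0) || all(b == 0)) {
    abort("s significance undefined for an entirely-hyperplane pattern",
          class = "syndromix_undefined_error")
  }
  null_s <- with_seed(seed, {
    bm <- replicate(n_perm, sample(b))
    s_index_many(a, bm)
  })
  p <- (1 + sum(null_s >= s_obs)) / (1 + n_perm)
  support <- sort(unique(null_s))
  tail_p <- (1 + n_perm - findInterval(support - 1e-12, sort(null_s))) / (1 + n_perm)
  crit_idx <- which(tail_p <= alpha)
  critical <- if (length(crit_idx) > 0) support[crit_idx[1]] else NA_real_
  list(p_value = p, critical_value = critical, n_perm = n_perm)
}

#' Critical value of s for a given salience regime
#'
#' Convenience wrapper around [s_significance()] that constructs two
#' patterns with the stated salience composition and reports the
#' permutation-null significance threshold at `alpha`. The default regime --
#' 8 of 24 variables salient, predominantly positive (7+/1-), in both
#' patterns -- is the classical one-third-salient calibration for
#' factor-matching over a two-thirds hyperplane, characteristic of consensus
#' syndromic patterns over a 24-variable battery.
#'
#' @param n_vars Number of variables (default 24).
#' @param pos_a,neg_a,pos_b,neg_b Salient counts by sign in each pattern.
#' @param n_perm,seed,alpha Passed to [s_significance()].
#' @return The critical s value (smallest s significant at `alpha`).
#' @export
#' @examples
#' \donttest{
#' s_critical(seed = 1)  # ~0.63 for 24-variable patterns
#' }
s_critical <- function(n_vars = 24, pos_a = 7, neg_a = 1, pos_b = 7, neg_b = 1,
                       n_perm = 10000, seed = 1, alpha = 0.05) {
  stopifnot(pos_a + neg_a <= n_vars, pos_b + neg_b <= n_vars)
  a <- c(rep(1L, pos_a), rep(-1L, neg_a), rep(0L, n_vars - pos_a - neg_a))
  b <- c(rep(1L, pos_b), rep(-1L, neg_b), rep(0L, n_vars - pos_b - neg_b))
  s_significance(1, a, b, n_perm = n_perm, seed = seed, alpha = alpha)$critical_value
}

# all permutations of 1..n in lexicographic order (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  dimnames(out) <- NULL
  out
}

#' Optimal alignment of two component loading matrices
#'
#' Component order and sign are arbitrary across extractions. This pairs the
#' components of `a` and `b` one-to-one to maximize total |congruence|
#' (exact assignment by exhaustive search, ties broken toward the smaller
#' component index), then flips the sign of each paired `b` component whose
#' congruence is negative. Order swaps (e.g. PC1 of one extraction matching
#' PC2 of the other) are explicit in the returned pairing; when the matrices
#' have unequal numbers of components, the surplus components are reported
#' as unmatched.
#'
#' @param a,b Loading matrices over the same variables (same row order).
#' @return A list of class `component_alignment`: `pairs` (tibble with
#'   `component_a`, `component_b`, `cc`, `flipped`), `b_aligned` (b's
#'   matched columns reordered/flipped to a's order), `unmatched_a`,
#'   `unmatched_b`.
#' @export
align_components <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    abort("loading matrices must cover the same variables", class = "syndromix_shape_error")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("variable names/order differ between matrices", class = "syndromix_shape_error")
  }
  k1 <- ncol(a); k2 <- ncol(b)
  cc <- matrix(0, k1, k2)
  for (i in seq_len(k1)) for (j in seq_len(k2)) cc[i, j] <- congruence(a[, i], b[, j])
  k <- min(k1, k2)
  # exhaustive assignment over the larger side's permutations
  if (k1 <= k2) {
    perms <- permutations_of(k2)
    best <- NULL; best_val <- -Inf
    for (r in seq_len(nrow(perms))) {
      sel <- perms[r, seq_len(k)]
      val <- sum(abs(cc[cbind(seq_len(k), sel)]))
      if (val > best_val + 1e-12) { best_val <- val; best <- sel }
    }
    pair_a <- seq_len(k); pair_b <- best
  } else {
    perms <- permutations_of(k1)
    best <- NULL; best_val <- -Inf
    for (r in seq_len(nrow(perms))) {
      sel <- perms[r, seq_len(k)]
      val <- sum(abs(cc[cbind(sel, seq_len(k))]))
      if (val > best_val + 1e-12) { best_val <- val; best <- sel }
    }
    ord <- order(best)
    pair_a <- best[ord]; pair_b <- seq_len(k)[ord]
  }
  cc_pair <- cc[cbind(pair_a, pair_b)]
  flipped <- cc_pair < 0
  b_aligned <- b[, pair_b, drop = FALSE] %*% diag(ifelse(flipped, -1, 1), k, k)
  dimnames(b_aligned) <- list(rownames(b), colnames(a)[pair_a])
  structure(
    list(
      pairs = tibble::tibble(
        component_a = pair_a,
        component_b = pair_b,
        cc = abs(cc_pair),
        flipped = flipped
      ),
      b_aligned = b_aligned,
      unmatched_a = setdiff(seq_len(k1), pair_a),
      unmatched_b = setdiff(seq_len(k2), pair_b)
    ),
    class = "component_alignment"
  )
}

#' Pattern-matching report for two loading matrices
#'
#' Aligns the component patterns (see [align_components()]) and computes all
#' four matching statistics per matched pair, with significance for r
#' (t test) and s (Monte-Carlo permutation null). A pair replicates by
#' consensus when all four agree: RMS at or below `rms_threshold`, CC at or
#' above `cc_threshold` (descriptive thresholds; no established significance
#' cutoffs exist for RMS/CC), and p < 0.05 for both r and s.
#'
#' @param a,b Loading matrices over the same variables (p x K1, p x K2), or
#'   `pc_model` objects.
#' @param threshold Salience cutoff for s (default 0.4).
#' @param n_perm Permutations for the s null (default 2000).
#' @param seed Integer seed.
#' @param cc_threshold,rms_threshold Descriptive consensus thresholds
#'   (defaults 0.90 and 0.20).
#' @return A tibble of class `match_report`, one row per matched pair:
#'   statistics, p-values, pass flags and `consensus_pass`; the alignment is
#'   attached as attribute `alignment`, unmatched components as attribute
#'   `unmatched`.
#' @export
match_report <- function(a, b, threshold = 0.4, n_perm = 2000, seed = 1,
                         cc_threshold = 0.90, rms_threshold = 0.20) {
  if (inherits(a, "pc_model")) a <- a$loadings
  if (inherits(b, "pc_model")) b <- b$loadings
  al <- align_components(a, b)
  k <- nrow(al$pairs)
  seeds <- derive_seeds(seed, k)
  rows <- purrr::map(seq_len(k), function(i) {
    va <- a[, al$pairs$component_a[i]]
    vb <- al$b_aligned[, i]
    lr <- loading_r(va, vb)
    sa <- salience_classify(va, threshold)
    sb <- salience_classify(vb, threshold)
    s <- if (all(sa == 0) && all(sb == 0)) NA_real_ else s_index(sa, sb)
    if (!is.na(s) && any(sa != 0) && any(sb != 0)) {
      sig <- s_significance(s, sa, sb, n_perm = n_perm, seed = seeds[i])
      p_s <- sig$p_value; s_crit <- sig$critical_value
    } else {
      p_s <- NA_real_; s_crit <- NA_real_
    }
    tibble::tibble(
      component_a = al$pairs$component_a[i],
      component_b = al$pairs$component_b[i],
      flipped = al$pairs$flipped[i],
      rms = rms_diff(va, vb),
      cc = congruence(va, vb),
      r = lr$r,
      p_r = lr$p_value,
      s = s,
      p_s = p_s,
      s_critical = s_crit
    )
  })
  out <- dplyr::bind_rows(rows)
  out$pass_rms <- out$rms <= rms_threshold
  out$pass_cc <- out$cc >= cc_threshold
  out$pass_r <- out$p_r < 0.05
  out$pass_s <- !is.na(out$p_s) & out$p_s < 0.05
  out$consensus_pass <- out$pass_rms & out$pass_cc & out$pass_r & out$pass_s
  attr(out, "alignment") <- al
  attr(out, "unmatched") <- list(a = al$unmatched_a, b = al$unmatched_b)
  class(out) <- c("match_report", class(tibble::tibble()))
  out
}
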