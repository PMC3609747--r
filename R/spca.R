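#' Soft-thresholding operator
#'
#' The shrinkage step underlying the lasso:
#' `sign(x) * pmax(|x| - delta, 0)`, elementwise.
#'
#' @param x Numeric vector.
#' @param delta Threshold (>= 0).
#' @return Shrunken vector.
#' @export
#' @examples
#' soft_threshold(c(2, -0.3), 0.5)  # 1.5 0
soft_threshold <- function(x, delta) {
  stopifnot(delta >= 0)
  sign(x) * pmax(abs(x) - delta, 0)
}

# smallest delta such that ||soft_threshold(x, delta)/||.||_2||_1 <= c,
# found by bisection (delta = 0 already feasible -> 0).
l1_bound_delta <- function(x, c, tol = 1e-8) {
  v <- x / sqrt(sum(x^2))
  if (sum(abs(v)) <= c) return(0)
  lo <- 0
  hi <- max(abs(x))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    sv <- soft_threshold(x, mid)
    n2 <- sqrt(sum(sv^2))
    l1 <- if (n2 == 0) 0 else sum(abs(sv)) / n2
    if (l1 > c) lo <- mid else hi <- mid
  }
  hi
}

#' Rank-1 penalized matrix decomposition with an L1-bounded loading vector
#'
#' Alternating maximization of `t(u) %*% x %*% v` subject to unit Euclidean
#' norms and `||v||_1 <= c` on the variable-side weights: `u` is the
#' normalized image `x %*% v`; `v` is the soft-thresholded image
#' `t(x) %*% u`, with the threshold chosen by bisection as the smallest
#' value enforcing the L1 bound. `c = sqrt(p)` recovers the unpenalized
#' leading component; `c = 1` forces a single nonzero weight. `v` starts at
#' the unpenalized leading right singular vector (deterministic warm start).
#'
#' @param x Centered (or standardized) data matrix, n x p.
#' @param c L1 bound on the variable weights, `1 <= c <= sqrt(p)`.
#' @param tol Convergence tolerance on v (default 1e-6).
#' @param max_iter Maximum alternating iterations (default 200).
#' @return A list: `u` (n), `v` (p, unit norm, `||v||_1 <= c`), `d`
#'   (`t(u) %*% x %*% v`, >= 0), `iterations`, `converged`.
#' @export
pmd_rank1 <- function(x, c, tol = 1e-6, max_iter = 200) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (c < 1 || c > sqrt(p) + 1e-9) {
    abort("penalty c must lie in [1, sqrt(p)]", class = "syndromix_domain_error")
  }
  sv <- svd(x, nu = 1, nv = 1)
  v <- sv$v[, 1]
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    xu <- x %*% v
    u <- xu / sqrt(sum(xu^2))
    xv <- drop(crossprod(x, u))
    delta <- l1_bound_delta(xv, c)
    vnew <- soft_threshold(xv, delta)
    vnew <- vnew / sqrt(sum(vnew^2))
    if (sqrt(sum((vnew - v)^2)) < tol) {
      v <- vnew
      converged <- TRUE
      break
    }
    v <- vnew
  }
  if (!converged) {
    warn(sprintf("pmd_rank1 did not converge in %d iterations", max_iter))
  }
  u <- drop(x %*% v)
  u <- u / sqrt(sum(u^2))
  d <- drop(crossprod(u, x %*% v))
  # orient deterministically: largest |v| entry positive
  i_max <- which.max(abs(v))
  if (v[i_max] < 0) { v <- -v; u <- -u }
  names(v) <- colnames(x)
  list(u = u, v = v, d = d, iterations = iter, converged = converged)
}

#' Sparse principal components by penalized matrix decomposition
#'
#' Extracts K sparse components by repeated rank-1 fits with deflation
#' (`x <- x - d * u %*% t(v)`); exact zeros in the loadings perform variable
#' subselection. Components are ordered by explained `d^2`. Note that
#' penalization can reorder components relative to the unpenalized
#' extraction; compare patterns via [align_components()].
#'
#' @param x An `analysis_matrix` (standardized internally; must be complete)
#'   or a centered/standardized numeric matrix.
#' @param c L1 bound, `1 <= c <= sqrt(p)`.
#' @param k Number of components.
#' @return An object of class `sparse_pc_model`: `loadings` (p x k sparse
#'   weight matrix), `d` (singular values), `nonzero` (per-component
#'   counts), `penalty`.
#' @export
spc_extract <- function(x, c, k = 3) {
  xm <- if (inherits(x, "analysis_matrix")) scale(matrix_values(x)) else as.matrix(x)
  if (anyNA(xm)) {
    abort("sparse PCA needs complete data; impute first", class = "syndromix_domain_error")
  }
  if (k > min(dim(xm))) {
    abort("k exceeds min(n, p)", class = "syndromix_domain_error")
  }
  cur <- xm
  comps <- purrr::map(seq_len(k), function(i) {
    fit <- pmd_rank1(cur, c)
    cur <<- cur - fit$d * tcrossprod(fit$u, fit$v)
    fit
  })
  ord <- order(purrr::map_dbl(comps, ~ .x$d^2), decreasing = TRUE)
  comps <- comps[ord]
  load <- do.call(cbind, purrr::map(comps, "v"))
  dimnames(load) <- list(colnames(xm), paste0("SPC", seq_len(k)))
  structure(
    list(
      loadings = load,
      d = purrr::map_dbl(comps, "d"),
      nonzero = colSums(load != 0),
      penalty = c
    ),
    class = "sparse_pc_model"
  )
}

#' @export
print.sparse_pc_model <- function(x, ...) {
  cat(sprintf("<sparse_pc_model> penalty c=%.3g, %d component(s), nonzero loadings: %s\n",
              x$penalty, ncol(x$loadings), paste(x$nonzero, collapse = ", ")))
  invisible(x)
}

#' Cross-validated selection of the sparse-PCA penalty
#'
#' Entry-wise holdout cross-validation: per fold, a random fraction of
#' matrix cells is held out (held-out cells are replaced by column means
#' during the fit), a rank-`k` sparse decomposition is fitted to the
#' remainder, the matrix is reconstructed, and the squared error on the
#' held-out cells accumulated. The penalty minimizing the mean held-out SSE
#' is selected. A holdout that empties a row or column is redrawn with a
#' warning.
#'
#' @param x An `analysis_matrix` or numeric matrix (standardized
#'   internally).
#' @param penalties Candidate L1 bounds (default: 8 values linearly spaced
#'   in `[1, sqrt(p)]`); at least 3.
#' @param folds Number of holdout folds (default 5).
#' @param holdout_fraction Fraction of entries held out per fold (default
#'   0.1).
#' @param k Components fitted per candidate (default 3).
#' @param seed Integer seed (deterministic given seed).
#' @return A list of class `spca_cv`: `profile` (tibble with `penalty`,
#'   `sse_mean`, `sse_sd`), `best` (selected penalty), `folds`, `seed`.
#' @export
cv_penalty <- function(x, penalties = NULL, folds = 5, holdout_fraction = 0.1,
                       k = 3, seed = 1) {
  xm <- if (inherits(x, "analysis_matrix")) scale(matrix_values(x)) else as.matrix(x)
  if (anyNA(xm)) {
    abort("cross-validation needs complete data; impute first",
          class = "syndromix_domain_error")
  }
  n <- nrow(xm); p <- ncol(xm)
  if (is.null(penalties)) penalties <- seq(1, sqrt(p), length.out = 8)
  if (length(penalties) < 3) {
    abort("need at least 3 candidate penalties", class = "syndromix_domain_error")
  }
  masks <- with_seed(seed, {
    purrr::map(seq_len(folds), function(f) {
      repeat {
        m <- matrix(runif(n * p) < holdout_fraction, n, p)
        if (all(rowSums(!m) > 0) && all(colSums(!m) > 0) && any(m)) return(m)
        warn("holdout emptied a row or column; resampling")
      }
    })
  })
  sse <- matrix(NA_real_, folds, length(penalties))
  for (f in seq_len(folds)) {
    m <- masks[[f]]
    xtrain <- xm
    xtrain[m] <- NA
    mu <- colMeans(xtrain, na.rm = TRUE)
    for (j in seq_len(p)) xtrain[is.na(xtrain[, j]), j] <- mu[j]
    for (ci in seq_along(penalties)) {
      fit <- spc_extract(xtrain, penalties[ci], k = k)
      u <- xtrain %*% fit$loadings
      # least-squares rank-k reconstruction given the sparse loadings
      # (tiny ridge guards against coinciding single-variable components)
      gram <- crossprod(fit$loadings) + 1e-8 * diag(k)
      recon <- u %*% solve(gram, t(fit$loadings))
      sse[f, ci] <- sum((recon[m] - xm[m])^2)
    }
  }
  profile <- tibble::tibble(
    penalty = penalties,
    sse_mean = colMeans(sse),
    sse_sd = apply(sse, 2, sd)
  )
  structure(
    list(profile = profile,
         best = penalties[which.min(profile$sse_mean)],
         folds = folds, seed = seed),
    class = "spca_cv"
  )
}

#' @export
print.spca_cv <- function(x, ...) {
  cat(sprintf("<spca_cv> selected penalty c=%.3g over %d candidates (%d folds)\n",
              x$best, nrow(x$profile), x$folds))
  invisible(x)
}
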