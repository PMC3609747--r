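#' Pearson cross-correlation matrix of an analysis matrix
#'
#' With complete data this is the ordinary Pearson correlation matrix. With
#' missing cells it delegates to [impute_missing()] and returns the pooled
#' correlation matrix (mean across completed datasets).
#'
#' @param x An `analysis_matrix`, data frame of numeric columns, or numeric
#'   matrix.
#' @param m,seed Passed to [impute_missing()] when missing cells are present.
#' @return A symmetric p x p correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, m = 5, seed = 1) {
  xm <- if (inherits(x, "analysis_matrix")) matrix_values(x) else as.matrix(x)
  if (nrow(xm) < 3) {
    abort("need at least 3 subjects", class = "syndromix_domain_error")
  }
  const <- apply(xm, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) == 0 || all(obs == obs[1])
  })
  if (any(const)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(xm)[const], collapse = ", ")),
          class = "syndromix_domain_error")
  }
  if (anyNA(xm)) {
    impute_missing(xm, m = m, seed = seed)$pooled_correlation
  } else {
    cor(xm)
  }
}

#' Principal component extraction from a correlation matrix
#'
#' Spectral decomposition of the cross-correlation matrix. The loading of
#' variable j on component k is `eigenvector[j,k] * sqrt(lambda_k)` -- i.e.
#' the Pearson correlation between the variable and the component score.
#' Eigenvalues below 1e-10 are clamped to zero; R is symmetrized as
#' `(R + t(R))/2` before decomposition. Each component's sign is oriented so
#' its largest-|loading| entry is positive (component signs are otherwise
#' arbitrary), making repeated extractions bit-reproducible.
#'
#' @param r Correlation matrix (symmetric positive semidefinite within
#'   tolerance).
#' @param k Number of components to keep, or `"all"`.
#' @return An object of class `pc_model`: `eigenvalues` (all p, descending),
#'   `loadings` (p x k), `variance_proportion` (`lambda/p`), `communalities`
#'   (row sums of squared retained loadings), `rotation = "none"`.
#' @export
#' @examples
#' r <- matrix(c(1, .6, .6, 1), 2, 2)
#' m <- pca_extract(r)
#' m$eigenvalues       # 1.6 0.4
#' m$loadings[, 1]     # ~0.894 0.894
pca_extract <- function(r, k = "all") {
  r <- as.matrix(r)
  if (max(abs(r - t(r))) > 1e-8) {
    abort("correlation matrix is not symmetric", class = "syndromix_domain_error")
  }
  r <- (r + t(r)) / 2
  p <- ncol(r)
  e <- eigen(r, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ev[ev < 1e-10] <- 0
  if (identical(k, "all")) k <- p
  k <- min(k, p)
  load <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev[seq_len(k)]), k, k)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  vn <- colnames(r)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  dimnames(load) <- list(vn, paste0("PC", seq_len(k)))
  structure(
    list(
      eigenvalues = ev,
      loadings = load,
      variance_proportion = ev / p,
      communalities = setNames(rowSums(load^2), vn),
      rotation = "none",
      scores = NULL
    ),
    class = "pc_model"
  )
}

#' Standardized component scores
#'
#' Projects z-scored data on the component directions and rescales each
#' score column to mean 0, SD 1 -- component scores are standardized to the
#' internal variance structure of the dataset they were extracted from.
#'
#' @param x Data whose columns match the model's variables: an
#'   `analysis_matrix` (z-scored internally; must be complete -- impute
#'   first) or a numeric matrix already z-scored by column.
#' @param model A `pc_model`.
#' @return An n x k matrix of standardized scores.
#' @export
compute_scores <- function(x, model) {
  xm <- if (inherits(x, "analysis_matrix")) {
    scale(matrix_values(x))
  } else {
    as.matrix(x)
  }
  if (ncol(xm) != nrow(model$loadings)) {
    abort("columns do not match the model's variables", class = "syndromix_shape_error")
  }
  if (!is.null(colnames(xm)) &&
      !identical(unname(colnames(xm)), unname(rownames(model$loadings)))) {
    abort("columns do not match the model's variables", class = "syndromix_shape_error")
  }
  if (anyNA(xm)) {
    abort("scores need complete data; impute first", class = "syndromix_domain_error")
  }
  raw <- xm %*% model$loadings
  sc <- scale(raw)
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  colnames(sc) <- colnames(model$loadings)
  sc
}

#' Kaiser retention rule
#'
#' Count of eigenvalues strictly greater than 1: each retained component
#' explains more than a single variable's worth of correlation-matrix
#' variance.
#'
#' @param eigenvalues Descending eigenvalues.
#' @return Integer count.
#' @export
retain_kaiser <- function(eigenvalues) {
  sum(eigenvalues > 1.0)
}

#' Automated scree (elbow) retention rule
#'
#' Formalizes the visual scree test as maximum acceleration: the elbow sits
#' at the interior index i maximizing the second difference
#' `lambda[i-1] - 2*lambda[i] + lambda[i+1]`; components before the elbow
#' (`i - 1` of them) are retained. Ties break to the smallest index
#' (fewest components).
#'
#' @param eigenvalues Descending eigenvalues, length >= 4.
#' @return Integer count.
#' @export
#' @examples
#' retain_scree(c(8, 5, 2.5, 1.1, 1.0, 0.95))  # 3
retain_scree <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p < 4) {
    abort("scree rule needs at least 4 eigenvalues", class = "syndromix_rule_error")
  }
  i <- 2:(p - 1)
  d2 <- eigenvalues[i - 1] - 2 * eigenvalues[i] + eigenvalues[i + 1]
  elbow <- i[which.max(d2)]  # which.max takes the first (smallest index) on ties
  elbow - 1L
}

#' Factor over-determination retention rule
#'
#' A component is interpretable only if enough variables load saliently on
#' it: counts the leading components with at least `min_salient` loadings of
#' absolute value strictly greater than `threshold`.
#'
#' @param loadings p x k loading matrix.
#' @param threshold Salience cutoff (default 0.4).
#' @param min_salient Minimum salient loadings per component (default 3).
#' @return Integer count (length of the leading qualifying run).
#' @export
retain_overdetermination <- function(loadings, threshold = 0.4, min_salient = 3) {
  ok <- colSums(abs(loadings) > threshold) >= min_salient
  sum(cumprod(ok))
}

#' Consensus component retention
#'
#' Applies the Kaiser, scree and over-determination rules and retains the
#' largest k such that components 1..k satisfy all three.
#'
#' @param eigenvalues Descending eigenvalues.
#' @param loadings Full loading matrix (used by the over-determination rule).
#' @param threshold,min_salient Passed to [retain_overdetermination()].
#' @return An object of class `retention_decision` with per-rule counts and
#'   `consensus`.
#' @export
retain_consensus <- function(eigenvalues, loadings, threshold = 0.4, min_salient = 3) {
  kaiser <- retain_kaiser(eigenvalues)
  scree <- retain_scree(eigenvalues)
  overdet <- retain_overdetermination(loadings, threshold, min_salient)
  structure(
    list(
      kaiser = kaiser,
      scree = scree,
      overdetermination = overdet,
      consensus = min(kaiser, scree, overdet),
      eigenvalues = eigenvalues,
      salient_counts = colSums(abs(loadings) > threshold),
      threshold = threshold,
      min_salient = min_salient
    ),
    class = "retention_decision"
  )
}

#' @export
print.retention_decision <- function(x, ...) {
  cat(sprintf("<retention_decision> kaiser=%d scree=%d overdetermination=%d -> consensus=%d\n",
              x$kaiser, x$scree, x$overdetermination, x$consensus))
  invisible(x)
}

#' Name a component by its salient loadings
#'
#' Lists the variables whose |loading| strictly exceeds the salience
#' threshold, sorted by magnitude, each tagged with its sign -- the set that
#' gives the component its interpretation.
#'
#' @param model A `pc_model`.
#' @param component Component index.
#' @param threshold Salience cutoff (default 0.4, strict).
#' @return A tibble with columns `variable`, `loading`, `sign`; empty (with
#'   a warning) when nothing is salient.
#' @export
name_component <- function(model, component, threshold = 0.4) {
  v <- model$loadings[, component]
  sal <- abs(v) > threshold
  if (!any(sal)) {
    warn(sprintf("component %d has no loading above |%.2f|", component, threshold))
  }
  out <- tibble::tibble(
    variable = names(v)[sal],
    loading = unname(v[sal]),
    sign = unname(ifelse(v[sal] > 0, "+", "-"))
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$loading)))
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion;
#' communalities are preserved. With a single component the model is
#' returned unchanged.
#'
#' @param model A `pc_model` with the retained components.
#' @return A `pc_model` with `rotation = "varimax"`.
#' @export
rotate_varimax <- function(model) {
  k <- ncol(model$loadings)
  if (k < 2) return(model)
  rot <- varimax(model$loadings, normalize = TRUE)
  load <- unclass(rot$loadings)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- dimnames(model$loadings)
  out <- model
  out$loadings <- load
  out$rotation <- "varimax"
  out
}

#' Promax (oblique) rotation of retained loadings
#'
#' Oblique rotation allowing correlated components; returns the pattern
#' matrix and the factor intercorrelations. When the underlying structure is
#' orthogonal the factor correlations are near zero and the pattern is close
#' to the varimax solution.
#'
#' @param model A `pc_model` with the retained components.
#' @param kappa Promax power (default 4).
#' @return A `pc_model` with `rotation = "promax"` and an extra element
#'   `factor_correlations` (k x k).
#' @export
rotate_promax <- function(model, kappa = 4) {
  k <- ncol(model$loadings)
  if (k < 2) {
    out <- model
    out$factor_correlations <- matrix(1, 1, 1)
    return(out)
  }
  rot <- promax(model$loadings, m = kappa)
  load <- unclass(rot$loadings)
  # factor correlations from the rotation matrix
  u <- solve(rot$rotmat)
  phi <- u %*% t(u)
  d <- sqrt(diag(phi))
  phi <- phi / outer(d, d)
  flip <- rep(1, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) flip[j] <- -1
  }
  load <- sweep(load, 2, flip, "*")
  phi <- diag(flip) %*% phi %*% diag(flip)
  dimnames(load) <- dimnames(model$loadings)
  dimnames(phi) <- list(colnames(load), colnames(load))
  out <- model
  out$loadings <- load
  out$rotation <- "promax"
  out$factor_correlations <- phi
  out
}

#' Full syndromic PCA of an analysis matrix
#'
#' The standard derivation path: pooled correlation matrix (multiple
#' imputation if cells are missing), full spectral decomposition, consensus
#' retention (Kaiser + scree + over-determination), truncation to the
#' retained components, and standardized subject scores (computed on the
#' mean of the completed datasets when imputation was needed).
#'
#' @param x An `analysis_matrix`.
#' @param k `"consensus"` (default) or an integer count of components.
#' @param threshold,min_salient Salience settings for retention/naming.
#' @param m,seed Imputation settings (only used when cells are missing).
#' @return A `pc_model` with `scores`, plus elements `retention`
#'   (a `retention_decision`) and `n`.
#' @export
#' @examples
#' dat <- syn_generate(syn_config(missing_rate = 0, seed = 3))
#' fit <- syndromic_pca(dat$matrix)
#' fit$retention$consensus
syndromic_pca <- function(x, k = "consensus", threshold = 0.4, min_salient = 3,
                          m = 5, seed = 1) {
  xm <- matrix_values(x)
  has_na <- anyNA(xm)
  if (has_na) {
    imp <- impute_missing(xm, m = m, seed = seed)
    r <- imp$pooled_correlation
    complete <- Reduce(`+`, imp$completions) / imp$m
  } else {
    r <- correlation_matrix(xm)
    complete <- xm
  }
  full <- pca_extract(r, "all")
  retention <- retain_consensus(full$eigenvalues, full$loadings,
                                threshold = threshold, min_salient = min_salient)
  kk <- if (identical(k, "consensus")) max(retention$consensus, 1L) else as.integer(k)
  model <- pca_extract(r, kk)
  model$scores <- compute_scores(scale(complete), model)
  rownames(model$scores) <- x$subject_id
  model$retention <- retention
  model$n <- nrow(xm)
  model
}

#' @export
print.pc_model <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("<pc_model> %d variables, %d component(s), rotation=%s\n",
              nrow(x$loadings), k, x$rotation))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_proportion[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}
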