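#' Tidy a principal component model
#'
#' @param x A `pc_model`.
#' @param ... Unused.
#' @return A tibble with one row per variable-component pair: `variable`,
#'   `component`, `loading`, `communality`, `salient` (|loading| > 0.4).
#' @export
tidy.pc_model <- function(x, ...) {
  out <- tibble::as_tibble(x$loadings, rownames = "variable")
  out <- tidyr::pivot_longer(out, -"variable", names_to = "component",
                             values_to = "loading")
  out$communality <- x$communalities[out$variable]
  out$salient <- abs(out$loading) > 0.4
  out
}

#' Glance at a principal component model
#'
#' @param x A `pc_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_variables`, `n_components`, `rotation`,
#'   `variance_explained` (cumulative proportion over the kept components),
#'   and the retention counts when available.
#' @export
glance.pc_model <- function(x, ...) {
  k <- ncol(x$loadings)
  out <- tibble::tibble(
    n_variables = nrow(x$loadings),
    n_components = k,
    rotation = x$rotation,
    variance_explained = sum(x$variance_proportion[seq_len(k)])
  )
  if (!is.null(x$retention)) {
    out$kaiser <- x$retention$kaiser
    out$scree <- x$retention$scree
    out$overdetermination <- x$retention$overdetermination
    out$consensus <- x$retention$consensus
  }
  out
}

#' Tidy a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return The report as a plain tibble (one row per matched component
#'   pair).
#' @export
tidy.match_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Glance at a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of matched pairs, number passing
#'   consensus, and counts of unmatched components on each side.
#' @export
glance.match_report <- function(x, ...) {
  un <- attr(x, "unmatched")
  tibble::tibble(
    n_pairs = nrow(x),
    n_consensus_pass = sum(x$consensus_pass, na.rm = TRUE),
    unmatched_a = length(un$a),
    unmatched_b = length(un$b)
  )
}

#' Tidy a group-effect report
#'
#' @param x A `group_effect`.
#' @param ... Unused.
#' @return The Tukey pairwise comparisons as a plain tibble.
#' @export
tidy.group_effect <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Glance at a group-effect report
#'
#' @param x A `group_effect`.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus F test (and covariate effect,
#'   for ANCOVA).
#' @export
glance.group_effect <- function(x, ...) {
  om <- attr(x, "omnibus")
  out <- tibble::tibble(f = om$f, df1 = om$df1, df2 = om$df2, p_value = om$p_value)
  cv <- attr(x, "covariate")
  if (!is.null(cv)) {
    out$covariate_slope <- cv$slope
    out$covariate_f <- cv$f
    out$covariate_p <- cv$p_value
  }
  out
}

#' Tidy a sparse principal component model
#'
#' @param x A `sparse_pc_model`.
#' @param ... Unused.
#' @return A tibble with one row per variable-component pair; zero loadings
#'   are kept explicit (they encode variable subselection).
#' @export
tidy.sparse_pc_model <- function(x, ...) {
  out <- tibble::as_tibble(x$loadings, rownames = "variable")
  tidyr::pivot_longer(out, -"variable", names_to = "component",
                      values_to = "loading")
}

#' Glance at a sparse principal component model
#'
#' @param x A `sparse_pc_model`.
#' @param ... Unused.
#' @return A one-row tibble: penalty, components, total nonzero loadings.
#' @export
glance.sparse_pc_model <- function(x, ...) {
  tibble::tibble(
    penalty = x$penalty,
    n_components = ncol(x$loadings),
    n_nonzero = sum(x$nonzero)
  )
}
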