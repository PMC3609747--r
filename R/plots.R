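#' Scree plot with retention annotations
#'
#' @param model A `pc_model` (ideally from [syndromic_pca()], so the
#'   retention decision is annotated).
#' @return A ggplot: eigenvalues against component rank, the Kaiser line at
#'   1, and the consensus retention count when available.
#' @export
plot_scree <- function(model) {
  df <- tibble::tibble(component = seq_along(model$eigenvalues),
                       eigenvalue = model$eigenvalues)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Component", y = "Eigenvalue") +
    ggplot2::theme_minimal()
  if (!is.null(model$retention)) {
    p <- p + ggplot2::geom_vline(xintercept = model$retention$consensus + 0.5,
                                 linetype = "dotted") +
      ggplot2::labs(subtitle = sprintf("consensus retention: %d component(s)",
                                       model$retention$consensus))
  }
  p
}

#' Loading heatmap of a (sparse) component model
#'
#' @param model A `pc_model` or `sparse_pc_model`.
#' @param threshold Salience cutoff marked on the fill scale (default 0.4).
#' @return A ggplot heat map of loadings (variables x components), diverging
#'   palette centred at zero.
#' @export
plot_loadings <- function(model, threshold = 0.4) {
  df <- tidy(model)
  df$variable <- factor(df$variable, levels = rev(rownames(model$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", limits = c(-1, 1)) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(abs(.data$loading) > threshold,
                                                   sprintf("%.2f", .data$loading), "")),
                       size = 2.6) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pc_model <- function(object, type = c("scree", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "scree") plot_scree(object) else plot_loadings(object, ...)
}

#' @export
autoplot.sparse_pc_model <- function(object, ...) {
  plot_loadings(object, ...)
}

#' @export
autoplot.spca_cv <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$penalty, y = .data$sse_mean)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$sse_mean - .data$sse_sd,
                                          ymax = .data$sse_mean + .data$sse_sd)) +
    ggplot2::geom_vline(xintercept = object$best, linetype = "dotted") +
    ggplot2::labs(x = "L1 penalty c", y = "held-out SSE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.match_report <- function(object, ...) {
  df <- tidy(object)
  df <- tidyr::pivot_longer(df[, c("component_a", "rms", "cc", "r", "s")],
                            -"component_a", names_to = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component_a), y = .data$value)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::facet_wrap(~.data$statistic, scales = "free_y") +
    ggplot2::labs(x = "component pair (by first matrix)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Subjects in the syndromic space spanned by two components
#'
#' @param model A `pc_model` with scores (from [syndromic_pca()]).
#' @param groups Group label per subject.
#' @param components Which two components to plot (default 1:2).
#' @return A ggplot scatter of standardized component scores coloured by
#'   group.
#' @export
plot_syndrome_space <- function(model, groups, components = c(1, 2)) {
  stopifnot(!is.null(model$scores), length(components) == 2)
  df <- tibble::tibble(
    x = model$scores[, components[1]],
    y = model$scores[, components[2]],
    group = groups
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = colnames(model$scores)[components[1]],
                  y = colnames(model$scores)[components[2]]) +
    ggplot2::theme_minimal()
}
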