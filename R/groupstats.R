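#' One-way ANOVA with Tukey posthocs on component scores
#'
#' Tests the sensitivity of a syndromic score to injury gradations: fixed-
#' effects one-way ANOVA of the score on group, followed by Tukey HSD
#' pairwise comparisons covering all group pairs. Significance at alpha =
#' 0.05 throughout.
#'
#' @param data Data frame with one row per subject.
#' @param score Column (tidy-eval) holding the component score.
#' @param group Column (tidy-eval) holding the group label.
#' @return A tibble of class `group_effect`, one row per group pair
#'   (`difference`, `p_adj`, `significant`), with the omnibus test attached
#'   as attribute `omnibus` (`f`, `df1`, `df2`, `p_value`) -- see
#'   [glance.group_effect()].
#' @export
#' @examples
#' d <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
#' anova_scores(d, y, g)
anova_scores <- function(data, score, group) {
  y <- dplyr::pull(data, {{ score }})
  g <- factor(dplyr::pull(data, {{ group }}))
  counts <- table(g)
  if (length(counts) < 2) {
    abort("need at least 2 groups", class = "syndromix_integrity_error")
  }
  if (any(counts < 2)) {
    abort(paste0("group(s) with fewer than 2 subjects: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "syndromix_integrity_error")
  }
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  omnibus <- list(
    f = an[["F value"]][1],
    df1 = an[["Df"]][1],
    df2 = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1]
  )
  tk <- TukeyHSD(fit)$g
  out <- tibble::tibble(
    comparison = rownames(tk),
    difference = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < 0.05
  )
  attr(out, "omnibus") <- omnibus
  attr(out, "covariate") <- NULL
  class(out) <- c("group_effect", class(tibble::tibble()))
  out
}

#' ANCOVA on component scores with a displacement covariate
#'
#' Linear model `score ~ covariate + group` with sequential sums of squares
#' (covariate first), so the group effect is covariate-adjusted: does injury
#' group still matter once standardized tissue displacement is corrected
#' for? Subjects without a defined covariate (shams, hemisections) are
#' dropped by default. Warns when the groups' covariate ranges do not
#' overlap (group comparison would rest on extrapolation).
#'
#' @param data Data frame with one row per subject.
#' @param score,group Columns (tidy-eval) as in [anova_scores()].
#' @param covariate Column (tidy-eval) holding the covariate (standardized
#'   displacement in microns).
#' @param drop_undefined Drop rows with `NA` covariate (default `TRUE`;
#'   `FALSE` raises an error if any are present).
#' @return A tibble of class `group_effect` (Tukey comparisons on the
#'   unadjusted group factor), with attributes `omnibus` (covariate-adjusted
#'   group test) and `covariate` (`slope`, `f`, `p_value`).
#' @export
ancova_scores <- function(data, score, group, covariate, drop_undefined = TRUE) {
  y <- dplyr::pull(data, {{ score }})
  g <- factor(dplyr::pull(data, {{ group }}))
  z <- dplyr::pull(data, {{ covariate }})
  if (anyNA(z)) {
    if (!drop_undefined) {
      abort("covariate missing for some subjects", class = "syndromix_domain_error")
    }
    keep <- !is.na(z)
    y <- y[keep]; g <- droplevels(g[keep]); z <- z[keep]
  }
  if (length(unique(z)) < 2) {
    abort("constant covariate", class = "syndromix_domain_error")
  }
  ranges <- tapply(z, g, range)
  lo <- max(purrr::map_dbl(ranges, 1))
  hi <- min(purrr::map_dbl(ranges, 2))
  if (lo > hi) {
    warn("groups do not overlap on the covariate; adjusted comparison extrapolates")
  }
  fit <- lm(y ~ z + g)
  an <- anova(fit)  # sequential: covariate first, group adjusted for it
  omnibus <- list(
    f = an["g", "F value"],
    df1 = an["g", "Df"],
    df2 = an["Residuals", "Df"],
    p_value = an["g", "Pr(>F)"]
  )
  cov_effect <- list(
    slope = unname(stats::coef(fit)["z"]),
    f = an["z", "F value"],
    p_value = an["z", "Pr(>F)"]
  )
  tk <- TukeyHSD(aov(y ~ g))$g
  out <- tibble::tibble(
    comparison = rownames(tk),
    difference = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < 0.05
  )
  attr(out, "omnibus") <- omnibus
  attr(out, "covariate") <- cov_effect
  class(out) <- c("group_effect", class(tibble::tibble()))
  out
}
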