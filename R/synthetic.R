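#' Default loading template for the synthetic outcome battery
#'
#' Returns the 24-variable, 3-factor loading template used by
#' [syn_generate()]. The template encodes the latent structure typical of
#' unilateral cervical contusion batteries: factor 1 ties tissue sparing to
#' gross behavioural recovery (all six histological measures, grooming, paw
#' placement, open-field locomotion, step-distribution deviations and body
#' weight); factor 2 captures fine motor control carried by digital gait
#' measures (print areas, forelimb stride length, BBB subscore); factor 3
#' links weight gain with hindlimb stride length. Lesion size and the
#' step-distribution deviations load negatively (worse outcome, less
#' sparing/recovery).
#'
#' Each variable also carries the affine map (`center`, `scale`) used to
#' express simulated standard scores on its native measurement scale, and a
#' `class` in behavioural/histological/health.
#'
#' @return A tibble with columns `variable`, `class`, `f1`, `f2`, `f3`,
#'   `center`, `scale`, `timepoints` (list column of assessment days).
#' @export
#' @examples
#' tpl <- syn_loading_template()
#' # communality bound holds for every variable
#' all(tpl$f1^2 + tpl$f2^2 + tpl$f3^2 < 1)
syn_loading_template <- function() {
  beh_days <- list(c(2, 7, 14, 21, 28, 42))
  gait_days <- list(c(21, 42))
  term_days <- list(42)
  tpl <- tibble::tribble(
    ~variable,             ~class,         ~f1,   ~f2,  ~f3,   ~center, ~scale,
    "grooming_left",        "behavioral",   0.55,  0,    0,      3.0,    1.2,
    "grooming_right",       "behavioral",   0.55,  0,    0,      3.0,    1.2,
    "paw_placement",        "behavioral",   0.58,  0,    0,     25,     10,
    "bbb",                  "behavioral",   0.58,  0,    0,     14,      4,
    "bbb_subscore",         "behavioral",   0.30,  0.66, 0,      6,      3,
    "forelimb_open_field",  "behavioral",   0.48,  0,    0,      2.5,    1,
    "stride_length_fl_l",   "behavioral",   0,     0.66, 0,     12,      2.5,
    "stride_length_fl_r",   "behavioral",   0,     0.66, 0,     12,      2.5,
    "stride_length_hl_l",   "behavioral",   0,     0,    0.90,  12,      2.5,
    "stride_length_hl_r",   "behavioral",   0,     0,    0.90,  12,      2.5,
    "print_area_fl_l",      "behavioral",   0,     0.88, 0,      1.6,    0.5,
    "print_area_fl_r",      "behavioral",   0,     0.88, 0,      1.6,    0.5,
    "print_area_hl_l",      "behavioral",   0,     0.88, 0,      1.6,    0.5,
    "print_area_hl_r",      "behavioral",   0,     0.88, 0,      1.6,    0.5,
    "step_dev_fl",          "behavioral",  -0.52,  0,    0,      8,      4,
    "step_dev_hl",          "behavioral",  -0.30,  0,   -0.60,   8,      4,
    "step_dev_total",       "behavioral",  -0.52,  0,    0,      8,      4,
    "lesion_size",          "histological",-0.82,  0,    0,     30,     12,
    "gm_sparing",           "histological", 0.82,  0,    0,     55,     18,
    "wm_sparing",           "histological", 0.82,  0,    0,     55,     18,
    "total_sparing",        "histological", 0.82,  0,    0,     55,     18,
    "total_area",           "histological", 0.82,  0,    0,     80,     15,
    "mn_sparing",           "histological", 0.82,  0,    0,     60,     20,
    "weight_change",        "health",       0.41,  0,    0.80,  10,     18
  )
  tpl$timepoints <- c(
    beh_days, beh_days, beh_days, beh_days, beh_days, beh_days,
    gait_days, gait_days, gait_days, gait_days,
    gait_days, gait_days, gait_days, gait_days,
    gait_days, gait_days, gait_days,
    term_days, term_days, term_days, term_days, term_days, term_days,
    term_days
  )
  tpl
}

#' Default injury-group design for the synthetic population
#'
#' Seven groups across three injury paradigms, with the group sizes of a
#' pooled two-site cervical SCI population (n = 159 in total): NYU/MASCIS
#' weight-drop (sham, 6.25 mm, 12.5 mm), Infinite Horizons force-controlled
#' (sham, 75 kdyn, 100 kdyn) and surgical hemisection. The `f1`--`f3` columns
#' are raw factor-score shifts: a severity gradient on factor 1 (12.5 mm most
#' severe), a hemisection-specific displacement on factor 2, and a
#' device-associated contrast on factor 3. Displacement columns give the
#' device-native impact displacement model (mean/SD, mm for NYU, micron for
#' IH; shams and hemisections have no displacement).
#'
#' @return A tibble with one row per group.
#' @export
syn_group_design <- function() {
  tibble::tribble(
    ~group,         ~device,        ~n,  ~f1,  ~f2,  ~f3, ~disp_mean, ~disp_sd, ~disp_unit,
    "sham_nyu",     "NYU",          10,  1.0,  0.2,  0.5,  NA,         NA,       NA,
    "nyu_6.25mm",   "NYU",          10,  0.0,  0.1,  0.5,  1.05,       0.12,     "mm",
    "nyu_12.5mm",   "NYU",          32, -1.0,  0.0,  0.4,  1.65,       0.18,     "mm",
    "sham_ih",      "IH",            6,  1.0,  0.2, -0.4,  NA,         NA,       NA,
    "ih_75kdyn",    "IH",           58, -0.2, -0.1, -0.4,  900,        90,       "micron",
    "ih_100kdyn",   "IH",           34, -0.7, -0.2, -0.5,  1120,       110,      "micron",
    "hemisection",  "HEMISECTION",   9, -0.5, -1.5,  0.2,  NA,         NA,       NA
  )
}

# Weighted Gram-Schmidt: center and orthogonalize the group-shift columns
# under the group-size weights, then rescale each factor's between-group SD.
# Keeps unequal n from inducing correlation between the latent factors.
orthogonalize_shifts <- function(shifts, n, sds) {
  w <- n / sum(n)
  m <- as.matrix(shifts)
  for (k in seq_len(ncol(m))) {
    m[, k] <- m[, k] - sum(w * m[, k])
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        m[, k] <- m[, k] - sum(w * m[, k] * m[, j]) / sum(w * m[, j]^2) * m[, j]
      }
    }
  }
  # a column whose residual is numerically zero (fewer groups than factors:
  # no independent contrast left) is dropped, not amplified
  scale0 <- sqrt(colSums(as.matrix(shifts)^2))
  for (k in seq_len(ncol(m))) {
    nk <- sqrt(sum(w * m[, k]^2))
    m[, k] <- if (nk > 1e-8 * max(scale0[k], 1)) m[, k] / nk * sds[k] else 0
  }
  m
}

#' Configuration for the synthetic outcome-battery generator
#'
#' Bundles and validates everything [syn_generate()] needs: the loading
#' template, the injury-group design, the between-group factor-shift SDs,
#' the missingness rate and the seed.
#'
#' @param group_design Tibble as returned by [syn_group_design()]; the `n`
#'   column may be edited to change group sizes.
#' @param loading_template Tibble as returned by [syn_loading_template()].
#' @param group_shift_sd Between-group standard deviation of the (weighted,
#'   orthogonalized) group factor shifts, one value per factor, in
#'   within-group SD units.
#' @param missing_rate Fraction of subject-by-variable cells masked missing
#'   completely at random, in `[0, 0.3]`.
#' @param displacement_r Within-group correlation between a subject's impact
#'   displacement and their factor-1 deviation (negative: deeper displacement,
#'   worse outcome).
#' @param seed Integer seed; the whole draw is a deterministic function of
#'   the configuration.
#' @return An object of class `syn_config`.
#' @export
#' @examples
#' cfg <- syn_config(missing_rate = 0, seed = 7)
#' sum(cfg$group_design$n)  # 159
syn_config <- function(group_design = syn_group_design(),
                       loading_template = syn_loading_template(),
                       group_shift_sd = c(0.35, 0.40, 0.45),
                       missing_rate = 0.10,
                       displacement_r = -0.6,
                       seed = 1) {
  stopifnot(is.data.frame(group_design), is.data.frame(loading_template))
  if (any(group_design$n < 1)) {
    abort("every group must have at least one subject", class = "syndromix_config_error")
  }
  lam <- as.matrix(loading_template[, c("f1", "f2", "f3")])
  comm <- rowSums(lam^2)
  if (any(comm >= 1)) {
    bad <- loading_template$variable[comm >= 1]
    abort(
      paste0("communality bound violated (sum of squared loadings >= 1) for: ",
             paste(bad, collapse = ", ")),
      class = "syndromix_config_error"
    )
  }
  n_sal <- colSums(abs(lam) > 0.4)
  if (any(n_sal < 3)) {
    abort("each factor needs at least 3 salient (|loading| > 0.4) variables",
          class = "syndromix_config_error")
  }
  if (missing_rate < 0 || missing_rate > 0.3) {
    abort("missing_rate must lie in [0, 0.3]", class = "syndromix_config_error")
  }
  if (length(group_shift_sd) != 3 || any(group_shift_sd < 0)) {
    abort("group_shift_sd must be 3 non-negative values", class = "syndromix_config_error")
  }
  structure(
    list(
      group_design = group_design,
      loading_template = loading_template,
      group_shift_sd = group_shift_sd,
      missing_rate = missing_rate,
      displacement_r = displacement_r,
      seed = as.integer(seed)
    ),
    class = "syn_config"
  )
}

#' Generate a synthetic outcome battery with known latent structure
#'
#' Draws subject factor scores as group shift + standard normal noise, builds
#' the outcome matrix `X = F %*% t(Lambda) + E` with independent normal
#' residuals whose SDs complete each variable's variance to 1, maps each
#' variable to its native scale affinely, masks cells missing completely at
#' random, and lays the result out both as a wide analysis matrix and as the
#' long-format outcome table that [read_outcomes()] parses (behavioural
#' values are repeated over their assessment days so time-averaging recovers
#' them exactly; trajectory shapes are not modelled).
#'
#' @param config A [syn_config()] object.
#' @return A list of class `syn_data` with elements `outcomes` (long tibble),
#'   `matrix` (an `analysis_matrix`), and `truth` (loading template matrix,
#'   factor scores, group labels, missingness mask, displacement values, and
#'   the population correlation matrix implied by the template).
#' @export
#' @examples
#' dat <- syn_generate(syn_config(seed = 42))
#' dim(dat$truth$factor_scores)
syn_generate <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  gd <- config$group_design
  tpl <- config$loading_template
  lam <- as.matrix(tpl[, c("f1", "f2", "f3")])
  rownames(lam) <- tpl$variable
  p <- nrow(tpl)
  n <- sum(gd$n)
  uniq_sd <- sqrt(1 - rowSums(lam^2))

  shifts <- orthogonalize_shifts(gd[, c("f1", "f2", "f3")], gd$n, config$group_shift_sd)

  with_seed(config$seed, {
    group <- rep(gd$group, gd$n)
    device <- rep(gd$device, gd$n)
    fscores <- matrix(rnorm(n * 3), n, 3) + shifts[rep(seq_len(nrow(gd)), gd$n), ]
    resid <- matrix(rnorm(n * p), n, p) %*% diag(uniq_sd)
    z <- fscores %*% t(lam) + resid
    colnames(z) <- tpl$variable

    # native scales (affine; correlation structure untouched)
    x <- sweep(sweep(z, 2, tpl$scale, "*"), 2, tpl$center, "+")

    # device displacement, correlated with the subject's factor-1 deviation
    r <- config$displacement_r
    disp_raw <- rep(NA_real_, n)
    disp_unit <- rep(NA_character_, n)
    f1_dev <- fscores[, 1] - shifts[rep(seq_len(nrow(gd)), gd$n), 1]
    for (g in seq_len(nrow(gd))) {
      idx <- which(group == gd$group[g])
      if (!is.na(gd$disp_mean[g])) {
        zq <- r * f1_dev[idx] + sqrt(1 - r^2) * rnorm(length(idx))
        disp_raw[idx] <- gd$disp_mean[g] + gd$disp_sd[g] * zq
        disp_unit[idx] <- gd$disp_unit[g]
      }
    }

    mask <- matrix(runif(n * p) < config$missing_rate, n, p)
    x[mask] <- NA_real_
  })

  subject_id <- sprintf("S%03d", seq_len(n))
  disp_microns <- ifelse(
    is.na(disp_raw), NA_real_,
    ifelse(disp_unit == "mm", disp_raw * 1000, disp_raw)
  )

  wide <- tibble::tibble(
    subject_id = subject_id,
    device = device,
    group = group,
    displacement_microns = disp_microns
  )
  wide <- dplyr::bind_cols(wide, tibble::as_tibble(x))
  amat <- new_analysis_matrix(wide, tibble::tibble(variable = tpl$variable, class = tpl$class))

  long <- tidyr::crossing(
    tibble::tibble(subject_id = subject_id, device = device, group = group,
                   displacement = disp_raw, displacement_unit = disp_unit),
    tibble::tibble(variable = tpl$variable)
  )
  long <- dplyr::left_join(
    long,
    tibble::tibble(variable = tpl$variable, variable_class = tpl$class,
                   timepoints = tpl$timepoints),
    by = "variable"
  )
  long <- tidyr::unnest_longer(long, "timepoints", values_to = "timepoint_days")
  vals <- tibble::as_tibble(x)
  vals$subject_id <- subject_id
  vals <- tidyr::pivot_longer(vals, -"subject_id",
                              names_to = "variable", values_to = "value")
  long <- dplyr::left_join(long, vals, by = c("subject_id", "variable"))
  long <- dplyr::select(
    long, "subject_id", "device", "group", "displacement", "displacement_unit",
    "variable", "variable_class", "timepoint_days", "value"
  )

  pop_cor <- lam %*% t(lam) + diag(uniq_sd^2)
  dimnames(pop_cor) <- list(tpl$variable, tpl$variable)

  structure(
    list(
      outcomes = long,
      matrix = amat,
      truth = list(
        loadings = lam,
        factor_scores = fscores,
        group = group,
        device = device,
        group_shifts = shifts,
        missing_mask = mask,
        displacement_raw = disp_raw,
        displacement_microns = disp_microns,
        population_correlation = pop_cor
      ),
      config = config
    ),
    class = "syn_data"
  )
}

#' Device-split scenario: two populations sharing one loading template
#'
#' Splits the default design into its NYU/MASCIS and Infinite Horizons
#' subpopulations (hemisections belong to neither device and are excluded),
#' and generates each with the same loading template but its own group-mean
#' structure and sample size. Used to test external validity: component
#' patterns extracted independently per device should replicate.
#'
#' @param config A [syn_config()]; its `group_design` must contain NYU and IH
#'   groups.
#' @param perturb Optional character vector of variables whose loadings are
#'   zeroed in the IH half only, to emulate a partially replicating
#'   component (e.g. right-forelimb print/stride measures).
#' @param split_shift_sd Between-group factor-shift SDs used within each
#'   device half. The default strengthens the severity separation on factor
#'   1 relative to the pooled default: within a single device the sham /
#'   moderate / severe contrast spans several within-group SDs on the
#'   primary recovery dimension, which is what anchors the leading
#'   component in each half.
#' @return A list of class `syn_split` with elements `nyu` and `ih`, each a
#'   `syn_data`.
#' @export
syn_device_split <- function(config = syn_config(), perturb = NULL,
                             split_shift_sd = c(2.0, 0.40, 0.45)) {
  stopifnot(inherits(config, "syn_config"))
  seeds <- derive_seeds(config$seed, 2)
  make_half <- function(dev, seed, perturb_vars = NULL) {
    gd <- config$group_design[config$group_design$device == dev, ]
    tpl <- config$loading_template
    if (!is.null(perturb_vars)) {
      hit <- tpl$variable %in% perturb_vars
      tpl[hit, c("f1", "f2", "f3")] <- 0
    }
    syn_generate(syn_config(
      group_design = gd,
      loading_template = tpl,
      group_shift_sd = split_shift_sd,
      missing_rate = config$missing_rate,
      displacement_r = config$displacement_r,
      seed = seed
    ))
  }
  structure(
    list(
      nyu = make_half("NYU", seeds[1]),
      ih = make_half("IH", seeds[2], perturb_vars = perturb)
    ),
    class = "syn_split"
  )
}

#' Null scenario: independent variables with no latent structure
#'
#' Generates an `analysis_matrix` of i.i.d. standard normal variables -- the
#' negative control for retention and pattern-matching: no component should
#' be retained by consensus, and no pattern should replicate against it.
#'
#' @param n Number of subjects.
#' @param p Number of variables (default 24).
#' @param seed Integer seed.
#' @return An `analysis_matrix`.
#' @export
syn_null <- function(n, p = 24, seed = 1) {
  x <- with_seed(seed, matrix(rnorm(n * p), n, p))
  vars <- sprintf("noise_%02d", seq_len(p))
  colnames(x) <- vars
  wide <- tibble::tibble(
    subject_id = sprintf("N%03d", seq_len(n)),
    device = rep("NYU", n),
    group = rep("null", n),
    displacement_microns = NA_real_
  )
  wide <- dplyr::bind_cols(wide, tibble::as_tibble(x))
  new_analysis_matrix(wide, tibble::tibble(variable = vars, class = "behavioral"))
}

#' @export
print.syn_data <- function(x, ...) {
  n <- nrow(x$matrix)
  p <- nrow(var_info(x$matrix))
  cat(sprintf("<syn_data> %d subjects x %d variables, %d groups, %.1f%% missing\n",
              n, p, length(unique(x$truth$group)),
              100 * mean(x$truth$missing_mask)))
  invisible(x)
}
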