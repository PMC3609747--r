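#' @title Outcome tables and analysis matrices
#' @description
#' Long-format outcome tables hold one record per subject, variable and
#' assessment day, plus subject metadata. The analysis matrix is the wide
#' subjects-by-variables table the multivariate machinery consumes: one
#' time-collapsed, normalized column per outcome, with missing cells kept
#' explicit (`NA`, never zero-filled).
#' @name outcome-io
NULL

outcome_columns <- c(
  "subject_id", "device", "group", "displacement", "displacement_unit",
  "variable", "variable_class", "timepoint_days", "value"
)

id_columns <- c("subject_id", "device", "group", "displacement_microns")

new_analysis_matrix <- function(data, var_info) {
  stopifnot(all(id_columns %in% names(data)), all(var_info$variable %in% names(data)))
  structure(data, var_info = var_info,
            class = c("analysis_matrix", class(tibble::tibble())))
}

#' Variable metadata of an analysis matrix
#'
#' @param x An `analysis_matrix`.
#' @return A tibble with columns `variable` and `class`
#'   (behavioral/histological/health).
#' @export
var_info <- function(x) {
  attr(x, "var_info")
}

# numeric matrix view (subjects x variables), rownames = subject ids
matrix_values <- function(x) {
  vi <- var_info(x)
  m <- as.matrix(as.data.frame(x)[, vi$variable, drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' Read a long-format outcome table
#'
#' Parses the package's long CSV dialect (UTF-8, "." decimal, header
#' required): columns `subject_id, device, group, displacement,
#' displacement_unit, variable, variable_class, timepoint_days, value`.
#' Empty fields and the literal `NA` are missing values; missing is never
#' coded as zero. Rows whose `value` or `timepoint_days` cannot be parsed
#' are rejected with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated outcome tibble.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "syndromix_format_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(outcome_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "syndromix_format_error")
  }
  parse_num <- function(s) {
    out <- suppressWarnings(as.numeric(s))
    out[s %in% c("", "NA")] <- NA_real_
    bad <- !(s %in% c("", "NA")) & is.na(out)
    list(value = out, bad = bad)
  }
  v <- parse_num(raw$value)
  t <- parse_num(raw$timepoint_days)
  d <- parse_num(raw$displacement)
  bad_rows <- which(v$bad | t$bad | d$bad)
  if (length(bad_rows) > 0) {
    abort(paste0("unparseable numeric value in row(s): ",
                 paste(head(bad_rows, 10), collapse = ", ")),
          class = "syndromix_format_error")
  }
  out <- tibble::tibble(
    subject_id = raw$subject_id,
    device = raw$device,
    group = raw$group,
    displacement = d$value,
    displacement_unit = dplyr::na_if(dplyr::na_if(raw$displacement_unit, ""), "NA"),
    variable = raw$variable,
    variable_class = raw$variable_class,
    timepoint_days = t$value,
    value = v$value
  )
  dup <- duplicated(out[, c("subject_id", "variable", "timepoint_days")])
  if (any(dup)) {
    k <- out[which(dup)[1], ]
    abort(sprintf("duplicate (subject, variable, timepoint) key: (%s, %s, %s)",
                  k$subject_id, k$variable, format(k$timepoint_days)),
          class = "syndromix_integrity_error")
  }
  out
}

#' Write a long-format outcome table
#'
#' @param outcomes Outcome tibble in the long dialect.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Collapse repeated measures over time
#'
#' Averages a variable's values over the requested assessment days, one value
#' per subject, to capture the temporal course in a single number. Days a
#' subject was not tested on contribute nothing; a subject with no available
#' requested day yields `NA`.
#'
#' @param outcomes Long outcome tibble.
#' @param variable Variable name.
#' @param timepoints Numeric vector of days post-op to average over.
#' @return A tibble with columns `subject_id` and `value`.
#' @export
#' @examples
#' tb <- tibble::tibble(
#'   subject_id = "a", device = "NYU", group = "sham_nyu",
#'   displacement = NA_real_, displacement_unit = NA_character_,
#'   variable = "bbb", variable_class = "behavioral",
#'   timepoint_days = c(7, 14, 21), value = c(2, 4, 6)
#' )
#' collapse_time(tb, "bbb", c(7, 14, 21))$value  # 4
collapse_time <- function(outcomes, variable, timepoints) {
  if (!variable %in% outcomes$variable) {
    abort(paste0("unknown variable: ", variable), class = "syndromix_lookup_error")
  }
  sub <- outcomes[outcomes$variable == variable &
                    outcomes$timepoint_days %in% timepoints, ]
  if (nrow(sub) == 0) {
    abort(paste0("no records at requested timepoints for: ", variable),
          class = "syndromix_lookup_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$subject_id),
    value = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out
}

#' Normalize a histological measure to the contralateral side
#'
#' Expresses an ipsilateral area or count as a percentage of the
#' contralateral (uninjured) control tissue.
#'
#' @param ipsilateral,contralateral Areas or counts (vectorized).
#' @return `100 * ipsilateral / contralateral`.
#' @export
#' @examples
#' normalize_histology(0.5, 1.0)  # 50
normalize_histology <- function(ipsilateral, contralateral) {
  if (any(contralateral <= 0, na.rm = TRUE)) {
    abort("contralateral reference must be positive", class = "syndromix_domain_error")
  }
  100 * ipsilateral / contralateral
}

#' Standardize impact displacement to microns across devices
#'
#' The NYU/MASCIS device reports displacement in mm, the IH device in
#' microns; this converts both to microns so displacement is comparable
#' across devices. Hemisection and sham subjects have no displacement: the
#' value propagates as `NA`.
#'
#' @param value Device-native displacement (vectorized).
#' @param device Character vector: `"NYU"`, `"IH"`, `"HEMISECTION"` or
#'   `"SHAM_ONLY"` (recycled if length 1).
#' @return Displacement in microns (`NA` where undefined).
#' @export
#' @examples
#' standardize_displacement(12.5, "NYU")  # 12500
standardize_displacement <- function(value, device) {
  if (length(device) == 1) device <- rep(device, length(value))
  stopifnot(length(device) == length(value))
  bad <- !device %in% c("NYU", "IH", "HEMISECTION", "SHAM_ONLY")
  if (any(bad)) {
    abort(paste0("unknown device: ", paste(unique(device[bad]), collapse = ", ")),
          class = "syndromix_domain_error")
  }
  if (any(value < 0, na.rm = TRUE)) {
    abort("displacement must be non-negative", class = "syndromix_domain_error")
  }
  out <- ifelse(device == "NYU", value * 1000,
                ifelse(device == "IH", value, NA_real_))
  as.numeric(out)
}

#' Default variable specification for matrix assembly
#'
#' One row per analysis-matrix column: which variable, its class, and the
#' assessment days to collapse over. Defaults mirror [syn_loading_template()].
#'
#' @return A tibble with columns `variable`, `class`, `timepoints` (list).
#' @export
default_variable_spec <- function() {
  tpl <- syn_loading_template()
  tibble::tibble(variable = tpl$variable, class = tpl$class, timepoints = tpl$timepoints)
}

#' Assemble the subjects-by-variables analysis matrix
#'
#' Builds one column per specified variable by time-collapsing its records
#' over the per-variable assessment days. Subjects are kept in first-seen
#' order; columns in spec order. Missing cells stay `NA`. A constant column
#' is an assembly error (it carries no correlation information); a subject
#' with an all-missing row is retained with a warning.
#'
#' @param outcomes Long outcome tibble.
#' @param spec Variable specification tibble (see [default_variable_spec()]);
#'   must name at least 2 variables.
#' @return An `analysis_matrix`.
#' @export
assemble_matrix <- function(outcomes, spec = default_variable_spec()) {
  if (nrow(spec) < 2) {
    abort("spec must name at least 2 variables", class = "syndromix_format_error")
  }
  missing_vars <- setdiff(spec$variable, unique(outcomes$variable))
  if (length(missing_vars) > 0) {
    abort(paste0("variable(s) absent from outcome table: ",
                 paste(missing_vars, collapse = ", ")),
          class = "syndromix_lookup_error")
  }
  subjects <- unique(outcomes$subject_id)
  meta <- dplyr::distinct(
    outcomes, .data$subject_id, .data$device, .data$group,
    .data$displacement, .data$displacement_unit
  )
  meta <- meta[match(subjects, meta$subject_id), ]
  disp_device <- ifelse(is.na(meta$displacement), meta$device,
                        ifelse(meta$displacement_unit == "mm", "NYU", "IH"))
  disp <- standardize_displacement(meta$displacement, disp_device)

  cols <- purrr::map(seq_len(nrow(spec)), function(i) {
    v <- collapse_time(outcomes, spec$variable[i], spec$timepoints[[i]])
    v$value[match(subjects, v$subject_id)]
  })
  names(cols) <- spec$variable
  x <- do.call(cbind, cols)

  const <- apply(x, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0 && all(obs == obs[1])
  })
  if (any(const)) {
    abort(paste0("constant column(s) after assembly: ",
                 paste(spec$variable[const], collapse = ", ")),
          class = "syndromix_integrity_error")
  }
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warn(paste0("subject(s) with all-missing rows retained: ",
                paste(subjects[all_missing], collapse = ", ")))
  }
  wide <- tibble::tibble(
    subject_id = subjects,
    device = meta$device,
    group = meta$group,
    displacement_microns = disp
  )
  wide <- dplyr::bind_cols(wide, tibble::as_tibble(x))
  new_analysis_matrix(wide, tibble::tibble(variable = spec$variable, class = spec$class))
}

#' Write an analysis matrix as a wide CSV
#'
#' @param x An `analysis_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Multiple imputation by iterative conditional regression
#'
#' Completes a matrix with sparse missingness `m` times. Each imputation
#' chain starts from column-mean fill and sweeps the columns repeatedly: the
#' column's missing entries are replaced by the linear prediction from all
#' other (currently completed) columns plus a stochastic normal residual
#' draw. Sweeping stops when column means move less than `tol` (or after
#' `sweeps` passes). The pooled correlation matrix is the mean of the `m`
#' completed-data correlation matrices. Deterministic given `seed`.
#'
#' @param x An `analysis_matrix` or numeric matrix with `NA`s.
#' @param m Number of imputations (default 5).
#' @param seed Integer seed.
#' @param sweeps Maximum sweeps per imputation (default 10).
#' @param tol Convergence tolerance on column means (default 1e-4).
#' @return A list of class `imputation_result`: `completions` (list of `m`
#'   numeric matrices), `pooled_correlation`, `m`, `seed`.
#' @export
impute_missing <- function(x, m = 5, seed = 1, sweeps = 10, tol = 1e-4) {
  xm <- if (inherits(x, "analysis_matrix")) matrix_values(x) else as.matrix(x)
  p <- ncol(xm)
  miss_frac <- colMeans(is.na(xm))
  if (any(miss_frac >= 0.5)) {
    bad <- colnames(xm)[miss_frac >= 0.5]
    abort(paste0("column(s) with >= 50% missing: ", paste(bad, collapse = ", ")),
          class = "syndromix_integrity_error")
  }
  na_idx <- which(is.na(xm))
  if (length(na_idx) == 0) {
    completions <- rep(list(xm), m)
    pooled <- cor(xm)
    return(structure(list(completions = completions, pooled_correlation = pooled,
                          m = m, seed = seed),
                     class = "imputation_result"))
  }
  mu <- colMeans(xm, na.rm = TRUE)
  miss_cols <- which(miss_frac > 0)

  completions <- with_seed(seed, {
    purrr::map(seq_len(m), function(im) {
      cur <- xm
      for (j in seq_len(p)) cur[is.na(xm[, j]), j] <- mu[j]
      prev_means <- colMeans(cur)
      for (s in seq_len(sweeps)) {
        for (j in miss_cols) {
          obs <- !is.na(xm[, j])
          design <- cbind(1, cur[, -j, drop = FALSE])
          fit <- lm.fit(design[obs, , drop = FALSE], xm[obs, j])
          coefs <- fit$coefficients
          coefs[is.na(coefs)] <- 0
          sigma <- sqrt(sum(fit$residuals^2) / max(1, sum(obs) - sum(!is.na(fit$coefficients))))
          pred <- design[!obs, , drop = FALSE] %*% coefs
          cur[!obs, j] <- pred + rnorm(sum(!obs), sd = sigma)
        }
        cur_means <- colMeans(cur)
        if (max(abs(cur_means - prev_means)) < tol) break
        prev_means <- cur_means
      }
      cur
    })
  })
  pooled <- Reduce(`+`, purrr::map(completions, cor)) / m
  pooled <- (pooled + t(pooled)) / 2
  diag(pooled) <- 1
  structure(list(completions = completions, pooled_correlation = pooled,
                 m = m, seed = seed),
            class = "imputation_result")
}
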