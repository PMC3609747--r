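#' @title Workflow orchestration
#' @description
#' The pipeline functions chain the package's stages -- simulate (or load),
#' assemble, derive, validate, sparse PCA -- writing plain-text artifacts
#' (CSV tables, JSON reports) with the seeds recorded, so a run is fully
#' reproducible from its configuration. All randomness funnels through one
#' master seed from which per-stage seeds are derived.
#' @name pipeline
NULL

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' @param outdir Output directory (created if needed).
#' @param config A [syn_config()].
#' @return Invisibly, the `syn_data`; writes `outcomes.csv` (long table),
#'   `matrix.csv` (wide matrix) and `truth.json` (loading template, group
#'   labels, seeds).
#' @export
pipeline_simulate <- function(outdir, config = syn_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dat <- syn_generate(config)
  write_outcomes(dat$outcomes, file.path(outdir, "outcomes.csv"))
  write_matrix(dat$matrix, file.path(outdir, "matrix.csv"))
  write_json_artifact(
    list(
      seed = config$seed,
      group_sizes = setNames(as.list(config$group_design$n), config$group_design$group),
      missing_rate = config$missing_rate,
      loadings = apply(dat$truth$loadings, 2, setNames, rownames(dat$truth$loadings),
                       simplify = FALSE)
    ),
    file.path(outdir, "truth.json")
  )
  invisible(dat)
}

#' Derive syndromic components and write the model artifacts
#'
#' @param x An `analysis_matrix` (e.g. from [assemble_matrix()] or
#'   [syn_generate()]).
#' @param outdir Output directory.
#' @param seed Master seed (imputation).
#' @param threshold,min_salient Salience settings.
#' @return Invisibly, the fitted `pc_model`; writes `loadings.csv`,
#'   `eigenvalues.csv`, `scores.csv`, `retention.json` and `naming.json`.
#' @export
pipeline_derive <- function(x, outdir, seed = 1, threshold = 0.4, min_salient = 3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fit <- syndromic_pca(x, threshold = threshold, min_salient = min_salient, seed = seed)
  readr::write_csv(tidy(fit), file.path(outdir, "loadings.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(component = seq_along(fit$eigenvalues),
                   eigenvalue = fit$eigenvalues,
                   variance_proportion = fit$variance_proportion),
    file.path(outdir, "eigenvalues.csv"), progress = FALSE
  )
  sc <- tibble::as_tibble(fit$scores)
  sc <- dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id,
                                        group = x$group, device = x$device), sc)
  readr::write_csv(sc, file.path(outdir, "scores.csv"), progress = FALSE)
  ret <- fit$retention
  write_json_artifact(
    list(seed = seed, kaiser = ret$kaiser, scree = ret$scree,
         overdetermination = ret$overdetermination, consensus = ret$consensus,
         eigenvalues = ret$eigenvalues, salient_counts = ret$salient_counts),
    file.path(outdir, "retention.json")
  )
  if (ret$consensus == 0) {
    warn("consensus retention is 0: no component satisfies all three rules")
  }
  naming <- purrr::map(seq_len(ncol(fit$loadings)), function(k) {
    nm <- suppressWarnings(name_component(fit, k, threshold))
    list(component = colnames(fit$loadings)[k],
         salient = purrr::pmap(nm, function(variable, loading, sign) {
           list(variable = variable, loading = loading, sign = sign)
         }))
  })
  write_json_artifact(list(seed = seed, threshold = threshold, components = naming),
                      file.path(outdir, "naming.json"))
  invisible(fit)
}

#' Run the validation battery and write its reports
#'
#' Variable-subset extractions (histology-only, behaviour-only), a case
#' split (by device when both devices are present), equalized-n
#' subsampling, and group-effect ANOVAs on the retained component scores.
#'
#' @param x An `analysis_matrix`.
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n_perm Permutations for s significance.
#' @param n_per_group,iterations Subsampling settings.
#' @return Invisibly, a list of the computed reports; writes
#'   `subset_*.csv`, `case_split.csv`, `consensus.csv`, `subsample.csv` and
#'   `group_effects.json`.
#' @export
pipeline_validate <- function(x, outdir, seed = 1, n_perm = 2000,
                              n_per_group = 9, iterations = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4)
  out <- list()

  for (cls in list(histology = "histological",
                   behavior = c("behavioral", "health"))) {
    nm <- if (identical(cls, "histological")) "histology" else "behavior"
    res <- subset_variable_pca(x, cls, seed = seeds[1], n_perm = n_perm)
    readr::write_csv(tibble::as_tibble(res$report),
                     file.path(outdir, paste0("subset_", nm, ".csv")),
                     progress = FALSE)
    out[[paste0("subset_", nm)]] <- res
  }

  if (length(unique(x$device[x$device %in% c("NYU", "IH")])) == 2) {
    keep <- x$device %in% c("NYU", "IH")
    xs <- new_analysis_matrix(x[keep, ], var_info(x))
    cs <- split_case_pca(xs, "device", seed = seeds[2], n_perm = n_perm)
    readr::write_csv(tibble::as_tibble(cs$report),
                     file.path(outdir, "case_split.csv"), progress = FALSE)
    readr::write_csv(cs$consensus, file.path(outdir, "consensus.csv"),
                     progress = FALSE)
    out$case_split <- cs
  }

  sub <- subsample_equalized(x, n_per_group = n_per_group,
                             iterations = iterations, seed = seeds[3],
                             undersized = "drop", n_perm = n_perm)
  readr::write_csv(sub$summary, file.path(outdir, "subsample.csv"), progress = FALSE)
  out$subsample <- sub

  fit <- syndromic_pca(x, seed = seeds[4])
  sc <- tibble::as_tibble(fit$scores)
  sc$group <- x$group
  effects <- purrr::map(colnames(fit$loadings), function(pc) {
    ge <- anova_scores(sc, !!rlang::sym(pc), .data$group)
    om <- attr(ge, "omnibus")
    list(component = pc, f = om$f, df1 = om$df1, df2 = om$df2, p_value = om$p_value)
  })
  write_json_artifact(list(seed = seed, anova = effects),
                      file.path(outdir, "group_effects.json"))
  out$group_effects <- effects
  invisible(out)
}

#' Sparse-PCA stage: penalty selection and sparse loading matrix
#'
#' @param x An `analysis_matrix` (complete; imputed internally when cells
#'   are missing, using the mean completed dataset).
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param penalties Candidate L1 bounds (default 8 values in
#'   `[1, sqrt(p)]`).
#' @param k Components.
#' @return Invisibly, a list with the `spca_cv` profile and the
#'   `sparse_pc_model` at the selected penalty; writes `cv_profile.csv` and
#'   `sparse_loadings.csv` (explicit zeros).
#' @export
pipeline_spca <- function(x, outdir, seed = 1, penalties = NULL, k = 3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  xm <- matrix_values(x)
  if (anyNA(xm)) {
    imp <- impute_missing(xm, seed = seed)
    xm <- Reduce(`+`, imp$completions) / imp$m
  }
  xs <- scale(xm)
  cv <- cv_penalty(xs, penalties = penalties, seed = seed, k = k)
  readr::write_csv(cv$profile, file.path(outdir, "cv_profile.csv"), progress = FALSE)
  fit <- spc_extract(xs, cv$best, k = k)
  ld <- tibble::as_tibble(fit$loadings)
  ld <- dplyr::bind_cols(tibble::tibble(variable = rownames(fit$loadings)), ld)
  readr::write_csv(ld, file.path(outdir, "sparse_loadings.csv"), progress = FALSE)
  write_json_artifact(list(seed = seed, selected_penalty = cv$best,
                           nonzero = as.list(setNames(fit$nonzero, colnames(fit$loadings)))),
                      file.path(outdir, "spca.json"))
  invisible(list(cv = cv, model = fit))
}

#' Run the full pipeline on simulated or supplied data
#'
#' Convenience orchestration: simulate (unless a matrix is supplied), then
#' derive, validate, and run the sparse-PCA stage, each into a subdirectory
#' of `outdir`.
#'
#' @param outdir Output directory.
#' @param x Optional `analysis_matrix`; when `NULL`, data are simulated from
#'   `config`.
#' @param config A [syn_config()] used when simulating.
#' @param seed Master seed for the analysis stages.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(outdir, x = NULL, config = syn_config(), seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(x)) {
    dat <- pipeline_simulate(file.path(outdir, "data"), config)
    x <- dat$matrix
  }
  seeds <- derive_seeds(seed, 3)
  list(
    derive = pipeline_derive(x, file.path(outdir, "derive"), seed = seeds[1]),
    validate = pipeline_validate(x, file.path(outdir, "validate"), seed = seeds[2]),
    spca = pipeline_spca(x, file.path(outdir, "spca"), seed = seeds[3])
  )
}
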