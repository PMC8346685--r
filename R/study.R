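#' End-to-end study driver
#'
#' Chains the full workflow on one cohort table: harmonize across sites,
#' run the repeated evaluation for each requested classifier, run the
#' permutation-null evaluation with the optimal hyperparameters, compute
#' per-metric permutation p-values and the between-model FDCI, and build
#' ROI importance maps.
#'
#' @name run_study
NULL

#' Study configuration
#'
#' @param positive,negative Group label sets defining the binary task.
#' @param modality `"structural"`, `"diffusion_FA"` or `"diffusion_RD"`.
#' @param models Character subset of `c("svc", "dlc")`.
#' @param R Evaluation repetitions (study-scale default 1000).
#' @param R_null Null repetitions (defaults to `R`).
#' @param master_seed Master seed; every random stage derives from it.
#' @param combat Logical: harmonize before evaluation.
#' @param combat_covariates Covariates in the harmonization design.
#' @param combat_restore Covariate effects restored after harmonization
#'   (default none: site, age and sex differences all minimized).
#' @param grid_svc,grid_dlc Optional [grid_spec()] overrides.
#' @param k Inner folds.
#' @return A `run_config` list.
#' @export
run_config <- function(positive, negative, modality = "diffusion_FA",
                       models = c("svc", "dlc"), R = 1000L, R_null = NULL,
                       master_seed = 1L, combat = TRUE,
                       combat_covariates = c("age", "sex"),
                       combat_restore = character(0),
                       grid_svc = NULL, grid_dlc = NULL, k = 10L) {
  models <- match.arg(models, several.ok = TRUE)
  bad <- setdiff(c(positive, negative), GROUP_LEVELS)
  if (length(bad))
    stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  structure(list(positive = positive, negative = negative,
                 modality = modality, models = models, R = as.integer(R),
                 R_null = as.integer(R_null %||% R),
                 master_seed = as.integer(master_seed), combat = combat,
                 combat_covariates = combat_covariates,
                 combat_restore = combat_restore,
                 grid_svc = grid_svc, grid_dlc = grid_dlc,
                 k = as.integer(k)),
            class = "run_config")
}

#' Run a complete classification study
#'
#' @param config A [run_config()].
#' @param cohort A [roi_cohort] (or path to a cohort table; the schema is
#'   then taken from `config$modality`).
#' @param outdir Optional directory; if given, summary JSON and CSV
#'   reports are written there.
#' @return A `study_report` list: `config`, `evaluation` (per model),
#'   `null` (per model), `significance` (per model), `fdci` (if both
#'   models), `importance` (per model), `combat_model`.
#' @export
run_study <- function(config, cohort, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) {
    schema <- switch(config$modality,
                     structural = build_structural_schema(),
                     diffusion_FA = build_diffusion_schema("FA"),
                     diffusion_RD = build_diffusion_schema("RD"))
    cohort <- load_cohort(cohort, schema)
  }
  cohort <- filter_complete_cases(cohort)
  combat_model <- NULL
  if (config$combat && length(unique(cohort$subjects$site)) > 1) {
    combat_model <- fit_combat(cohort,
                               covariates = config$combat_covariates)
    cohort <- apply_combat(combat_model, cohort,
                           restore = config$combat_restore)
  }
  task <- select_binary_groups(cohort, config$positive, config$negative)
  seeds <- derive_seeds(config$master_seed, 2L * length(config$models),
                        salt = 31L)

  evaluation <- list(); null <- list(); signif <- list(); imp <- list()
  for (i in seq_along(config$models)) {
    kind <- config$models[i]
    grid <- if (kind == "svc") config$grid_svc else config$grid_dlc
    evaluation[[kind]] <- run_repeated_evaluation(
      task$cohort, task$labels, kind = kind, grid = grid, R = config$R,
      master_seed = seeds[2 * i - 1], k = config$k)
    null[[kind]] <- run_null_evaluation(
      task$cohort, task$labels, kind = kind,
      fixed_params = modal_params(evaluation[[kind]]), R = config$R_null,
      master_seed = seeds[2 * i], k = config$k)
    signif[[kind]] <- significance_report(evaluation[[kind]], null[[kind]])
    imp[[kind]] <- if (kind == "svc")
      svc_importance(evaluation[[kind]]$models, cohort$schema)
    else dlc_importance(evaluation[[kind]]$models, cohort$schema)
  }
  fdci <- if (all(c("svc", "dlc") %in% config$models))
    compute_fdci(evaluation$svc$metrics$ACC, evaluation$dlc$metrics$ACC)
  else NULL

  report <- structure(list(config = config, evaluation = evaluation,
                           null = null, significance = signif, fdci = fdci,
                           importance = imp, combat_model = combat_model),
                      class = "study_report")
  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

#' Write a study report bundle to disk
#'
#' Per model: per-iteration metrics CSV, null metrics CSV, significance
#' CSV and importance CSV; plus one `summary.json` embedding the resolved
#' configuration and seeds.
#'
#' @param report A `study_report`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    config = report$config[setdiff(names(report$config),
                                   c("grid_svc", "grid_dlc"))],
    models = list())
  for (kind in names(report$evaluation)) {
    ev <- report$evaluation[[kind]]
    data.table::fwrite(ev$metrics,
                       file.path(outdir, sprintf("metrics_%s.csv", kind)))
    data.table::fwrite(report$null[[kind]]$metrics,
                       file.path(outdir, sprintf("null_%s.csv", kind)))
    data.table::fwrite(report$significance[[kind]],
                       file.path(outdir,
                                 sprintf("significance_%s.csv", kind)))
    export_importance(report$importance[[kind]],
                      file.path(outdir, sprintf("importance_%s.csv", kind)))
    summary$models[[kind]] <- list(
      mean = as.list(ev$mean), sd = as.list(ev$sd), R = ev$R,
      master_seed = ev$master_seed,
      optimal_params = modal_params(ev),
      p_values = stats::setNames(as.list(report$significance[[kind]]$p),
                                 report$significance[[kind]]$metric))
  }
  if (!is.null(report$fdci)) summary$fdci <- report$fdci
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> task: {%s} vs {%s}\n",
              paste(x$config$positive, collapse = ","),
              paste(x$config$negative, collapse = ",")))
  for (kind in names(x$evaluation)) {
    ev <- x$evaluation[[kind]]
    cat(sprintf("  %s: ACC %.3f +/- %.3f (R = %d), p[ACC] = %.4g\n",
                toupper(kind), ev$mean[["ACC"]], ev$sd[["ACC"]], ev$R,
                x$significance[[kind]]$p[
                  x$significance[[kind]]$metric == "ACC"]))
  }
  if (!is.null(x$fdci))
    cat(sprintf("  FDCI (SVC vs DLC): %.3f\n", x$fdci$fdci))
  invisible(x)
}
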