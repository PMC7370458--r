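#' Configure a full mapping-study replica
#'
#' Bundles the settings of every stage: the synthetic cohort, the mapping
#' families to estimate, the cross-validation design and the
#' cost-effectiveness comparison.
#'
#' @param cohort A [cohort_spec()].
#' @param families Mapping families to fit (subset of `1:6` or names).
#' @param k Cross-validation folds.
#' @param cea_time_obs,cea_time_trt,cea_subsequent,cea_delta_cost,cea_n_samples
#'   Parameters of the two-arm cost-effectiveness layer (see
#'   [cea_config()]); `cea_subsequent` is used for both arms.
#' @param seed Master seed; every stage derives its own substream.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort = cohort_spec(), families = 1:6, k = 5,
                         cea_time_obs = 0.65, cea_time_trt = 0.87,
                         cea_subsequent = 0.8, cea_delta_cost = 30163,
                         cea_n_samples = 10000L, seed = 1L) {
  structure(list(cohort = cohort,
                 families = vapply(families, normalize_family, character(1)),
                 k = k,
                 cea = list(time_obs = cea_time_obs, time_trt = cea_time_trt,
                            subsequent = cea_subsequent,
                            delta_cost = cea_delta_cost,
                            n_samples = as.integer(cea_n_samples)),
                 seed = as.integer(seed)),
            class = "study_config")
}

stage <- function(name, expr, log = TRUE) {
  if (log) message(format(Sys.time(), "%H:%M:%S"), " stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full mapping study end-to-end
#'
#' Executes, in order: cohort simulation, questionnaire scoring, full-data
#' estimation of each requested mapping family (with backward selection
#' and sign pruning), k-fold cross-validation per family,
#' incomplete-questionnaire evaluation for the scale-score families, and
#' the two-arm cost-effectiveness comparison of utility sources (observed
#' vs each mapped source, patients randomised to pseudo-arms). All
#' randomness derives from the master seed, so a re-run reproduces the
#' report byte-for-byte. Each stage failure halts with an error naming
#' the stage.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory: writes `report.json`, the
#'   fitted coefficient files under `models/`, and the exported CSV
#'   tables.
#' @param quiet Suppress stage log messages.
#' @return A `study_report` list: `cv` (per-family reports), `fits`,
#'   `cv_table`, `incomplete_table`, `cea_table`, `provenance`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  log <- !quiet

  cohort <- stage("simulate", generate_cohort(config$cohort, seed), log)
  vs <- resolve_value_set(attr(cohort, "value_set"))
  complete <- cohort[cohort$complete, , drop = FALSE]
  scored <- stage("score", score_qlqc30(complete), log)
  full <- cbind(complete, scored[, qlq_scale_names(), drop = FALSE])

  fits <- stage("fit", {
    out <- list()
    for (fam in config$families)
      out[[fam]] <- fit_family(full, fam, vs = vs)
    out
  }, log)

  cv <- stage("validate", {
    out <- list()
    for (fam in config$families)
      out[[fam]] <- cross_validate(fam, cohort, k = config$k, seed = seed,
                                   vs = vs)
    out
  }, log)

  scale_fams <- intersect(config$families,
                          c("scale_scores", "response_mapping", "beta",
                            "separate_equations"))
  incomplete_table <- if (length(scale_fams) && any(!cohort$complete)) {
    stage("incomplete",
          evaluate_incomplete(cohort, fits[scale_fams], vs = vs), log)
  } else NULL

  cea <- stage("cea", {
    set.seed(substream_seed(seed, "arms"))
    pats <- unique(complete$patient_id)
    trt_pats <- sample(pats, floor(length(pats) / 2))
    arm <- ifelse(full$patient_id %in% trt_pats, "trt", "obs")
    summarise <- function(u, a) c(mean(u[arm == a]),
                                  stats::sd(u[arm == a]) / sqrt(sum(arm == a)))
    sources <- list(observed = list(obs = summarise(full$utility, "obs"),
                                    trt = summarise(full$utility, "trt")))
    for (fam in config$families) {
      p <- predict_mapped(fits[[fam]], full, vs = vs)
      sources[[fam]] <- list(obs = summarise(p, "obs"),
                             trt = summarise(p, "trt"))
    }
    cfg <- cea_config(utility_obs = sources$observed$obs,
                      utility_trt = sources$observed$trt,
                      time_obs = config$cea$time_obs,
                      time_trt = config$cea$time_trt,
                      subsequent_obs = config$cea$subsequent,
                      subsequent_trt = config$cea$subsequent,
                      delta_cost = config$cea$delta_cost,
                      n_samples = config$cea$n_samples)
    compare_utility_sources(sources, cfg, seed = seed)
  }, log)

  cv_table <- cv_comparison_table(cv, full$utility)

  report <- structure(list(
    cv = cv, fits = fits, cv_table = cv_table,
    incomplete_table = incomplete_table,
    cea_table = cea$table, cea = cea$results,
    provenance = list(seed = seed,
                      n_complete = nrow(complete),
                      n_incomplete = sum(!cohort$complete),
                      families = config$families,
                      k = config$k,
                      value_set = vs$name,
                      package_version = as.character(
                        utils::packageVersion("qolmap")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."))
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "models"), recursive = TRUE,
               showWarnings = FALSE)
    for (fam in config$families)
      save_mapping_model(fits[[fam]],
                         file.path(out_dir, "models",
                                   paste0(fam, ".json")),
                         name = fam, tariff = vs$name)
    export_tables(report, out_dir)
    jsonlite::write_json(report_as_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Serializable view of a study report (no closures, no fitted objects).
report_as_json <- function(report) {
  list(
    provenance = report$provenance,
    cv_table = report$cv_table,
    incomplete_table = report$incomplete_table,
    cea_table = report$cea_table,
    fold_metrics = lapply(report$cv, function(r) r$fold_metrics),
    selection_history = lapply(report$fits, function(f)
      if (inherits(f, "qolmap_fit")) f$history else NULL)
  )
}

cv_comparison_table <- function(cv, observed) {
  obs <- data.frame(n = length(observed), mean = mean(observed),
                    sd = stats::sd(observed), min = min(observed),
                    max = max(observed), rmse = NA_real_, mae = NA_real_,
                    spearman = NA_real_, t_p = NA_real_)
  tab <- cbind(data.frame(model = "observed"), obs)
  for (nm in names(cv))
    tab <- rbind(tab, cbind(data.frame(model = nm), cv[[nm]]$pooled))
  rownames(tab) <- NULL
  tab
}

#' Export the study report as three-decimal CSV tables
#'
#' Writes `table_cv.csv` (pooled cross-validated performance per model,
#' observed column first), `table_incomplete.csv` (performance on
#' incomplete questionnaires) and `table_cea.csv` (ICER per utility
#' source with differences vs the observed reference). Numeric cells are
#' rounded to 3 decimals (ICERs to whole EUR); re-export is idempotent.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round_df <- function(df, digits = 3) {
    for (j in seq_along(df)) if (is.numeric(df[[j]]))
      df[[j]] <- round(df[[j]], digits)
    df
  }
  paths <- character(0)
  p <- file.path(dir, "table_cv.csv")
  utils::write.csv(round_df(report$cv_table), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$incomplete_table)) {
    p <- file.path(dir, "table_incomplete.csv")
    utils::write.csv(round_df(report$incomplete_table), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  cea <- report$cea_table
  for (col in c("icer", "ci_low", "ci_high", "icer_diff"))
    cea[[col]] <- round(cea[[col]])
  p <- file.path(dir, "table_cea.csv")
  utils::write.csv(round_df(cea), p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Mapping study report (seed ", x$provenance$seed, ", n = ",
      x$provenance$n_complete, " complete + ", x$provenance$n_incomplete,
      " incomplete)\n\n", sep = "")
  cat("Cross-validated performance (pooled over held-out folds):\n")
  print(x$cv_table, digits = 3)
  if (!is.null(x$incomplete_table)) {
    cat("\nIncomplete questionnaires:\n")
    print(x$incomplete_table, digits = 3)
  }
  cat("\nICER by utility source:\n")
  print(x$cea_table, digits = 4)
  invisible(x)
}
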