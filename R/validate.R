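#' Random fold assignment for cross-validation
#'
#' Row-level mode partitions the rows uniformly at random into `k` folds
#' whose sizes differ by at most one (remainder rows go to the
#' lowest-index folds). Patient-level mode keeps all rows of a patient in
#' one fold (assigning shuffled patients to the currently smallest fold),
#' avoiding leakage of within-patient correlation between training and
#' test folds.
#'
#' @param n_rows Number of rows.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param grouping `"row"` or `"patient"`.
#' @param patient_id Patient key per row (patient-level mode).
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(n_rows, k = 5, seed = 1L,
                       grouping = c("row", "patient"), patient_id = NULL) {
  grouping <- match.arg(grouping)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n_rows) stop("k exceeds the number of rows", call. = FALSE)
  set.seed(substream_seed(seed, "folds"))
  if (grouping == "row") {
    sizes <- rep(n_rows %/% k, k)
    rem <- n_rows - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
    fold <- integer(n_rows)
    fold[sample.int(n_rows)] <- rep(seq_len(k), times = sizes)
  } else {
    if (is.null(patient_id))
      stop("patient-level folding needs patient_id", call. = FALSE)
    pats <- sample(unique(patient_id))
    rows_per <- table(patient_id)[as.character(pats)]
    load <- numeric(k)
    assign <- integer(length(pats))
    for (i in seq_along(pats)) {
      j <- which.min(load)
      assign[i] <- j
      load[j] <- load[j] + rows_per[i]
    }
    fold <- assign[match(patient_id, pats)]
  }
  fold
}

#' Prediction performance metrics
#'
#' Summarises predictions against observations: mean, SD, min and max of
#' the predictions; RMSE; MAE; Spearman rank correlation (average ranks on
#' ties); and the p-value of a two-sided t-test of predicted versus
#' observed (paired by default). With zero-variance differences (e.g.
#' perfect prediction) the t-test p-value is undefined and reported as
#' `NA` with a warning, as is Spearman correlation when either vector is
#' constant.
#'
#' @param observed,predicted Equal-length numeric vectors (pairs with any
#'   `NA` are dropped; at least 2 complete pairs required).
#' @param paired Paired t-test (default) or two-sample.
#' @return One-row data frame: `n`, `mean`, `sd`, `min`, `max`, `rmse`,
#'   `mae`, `spearman`, `t_p`.
#' @export
compute_metrics <- function(observed, predicted, paired = TRUE) {
  if (length(observed) != length(predicted))
    stop("observed and predicted have different lengths", call. = FALSE)
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2) stop("need at least 2 non-missing pairs", call. = FALSE)
  err <- p - o
  rho <- if (stats::sd(o) == 0 || stats::sd(p) == 0) {
    warning("Spearman correlation undefined for constant input",
            call. = FALSE)
    NA_real_
  } else suppressWarnings(stats::cor(o, p, method = "spearman"))
  t_p <- if (paired && stats::sd(err) == 0) {
    warning("t-test undefined: zero-variance differences", call. = FALSE)
    NA_real_
  } else {
    tryCatch(stats::t.test(p, o, paired = paired)$p.value,
             error = function(e) {
               warning("t-test undefined: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }
  data.frame(n = length(o), mean = mean(p), sd = stats::sd(p),
             min = min(p), max = max(p),
             rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
             spearman = rho, t_p = t_p)
}

#' Fit one mapping family end-to-end
#'
#' Dispatches to the family's full estimation procedure, applying
#' backward selection and non-logical-coefficient pruning where the
#' family prescribes them (families 1--3 and 5, and the linear parts of
#' 6; the response-mapping family and the multinomial step of the
#' separate-equations family are exempt).
#'
#' @param data Data frame with utility, cluster key and the family's
#'   predictors (items and/or scale scores).
#' @param family `1`..`6`, or one of `"scale_scores"`,
#'   `"continuous_items"`, `"item_dummies"`, `"response_mapping"`,
#'   `"beta"`, `"separate_equations"`.
#' @param vs Value set (kept for interface symmetry; fitting itself is
#'   tariff-free).
#' @param alpha Selection cut-off.
#' @param select Apply selection + pruning (default TRUE).
#' @return A fitted mapping model (`qolmap_fit`,
#'   `response_mapping_model` or `separate_equations_model`).
#' @export
fit_family <- function(data, family, vs = NULL, alpha = 0.05,
                       select = TRUE) {
  key <- normalize_family(family)
  switch(key,
    scale_scores = ,
    continuous_items = ,
    item_dummies = {
      f <- fit_linear(data, key)
      if (select) f <- prune_nonlogical(backward_select(f, alpha),
                                        alpha = alpha)
      f
    },
    response_mapping = fit_response_mapping(data),
    beta = {
      f <- fit_beta(data)
      if (select) f <- prune_nonlogical(backward_select(f, alpha),
                                        alpha = alpha)
      f
    },
    separate_equations = fit_separate_equations(data, select = select,
                                                alpha = alpha)
  )
}

# Attach the 15 scale scores, scoring raw items when present; a table that
# already carries scale-score columns passes through unchanged.
with_scale_scores <- function(data) {
  if (all(qlq_item_names() %in% names(data))) {
    scored <- score_qlqc30(data)
    keep <- setdiff(qlq_scale_names(), names(data))
    return(cbind(data, scored[, keep, drop = FALSE]))
  }
  if (!any(qlq_scale_names() %in% names(data)))
    stop("data provide neither QLQ-C30 items nor scale scores",
         call. = FALSE)
  data
}

normalize_family <- function(family) {
  key <- as.character(family)
  map <- c(`1` = "scale_scores", `2` = "continuous_items",
           `3` = "item_dummies", `4` = "response_mapping",
           `5` = "beta", `6` = "separate_equations")
  if (key %in% names(map)) return(unname(map[key]))
  if (key %in% map) return(key)
  stop("unknown mapping family '", family, "'", call. = FALSE)
}

family_label <- function(key) {
  c(scale_scores = "model 1 (RE, scale scores)",
    continuous_items = "model 2 (RE, continuous items)",
    item_dummies = "model 3 (RE, item dummies)",
    response_mapping = "model 4 (ordered logit)",
    beta = "model 5 (beta regression)",
    separate_equations = "model 6 (separate equations)")[[key]]
}

# Predictors a fitted family needs at prediction time.
required_predictors <- function(fit) {
  model <- if (inherits(fit, "qolmap_fit")) fit$model else fit
  if (inherits(model, "response_mapping_model")) return(model$predictors)
  if (inherits(model, "separate_equations_model")) {
    coef_of <- function(x)
      if (inherits(x, "qolmap_fit")) x$model$coefficients else x$coefficients
    return(unique(c(model$candidates, names(coef_of(model$low)),
                    names(coef_of(model$mid)))))
  }
  names(model$coefficients)
}

#' Cross-validate a mapping family
#'
#' Splits the complete records into `k` folds, re-runs the family's full
#' fitting procedure (including backward selection and sign pruning) on
#' each training set of `k - 1` folds, predicts the held-out fold, and
#' reports per-fold and pooled performance metrics over the concatenated
#' held-out predictions. A fitting failure in a fold is flagged in the
#' report instead of being silently pooled.
#'
#' @param family Mapping family (`1`..`6` or name).
#' @param cohort Cohort of complete records (items + domains + utility, as
#'   from [generate_cohort()]).
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param vs Value set used to score response-mapping predictions
#'   (defaults to the cohort's generating tariff, else the Dutch tariff).
#' @param grouping Fold grouping, see [make_folds()].
#' @param mode Response-mapping scoring mode.
#' @return A `cv_report`: `family`, `fold_metrics`, `pooled`,
#'   `predictions` (observed, predicted, fold), `failed_folds`.
#' @export
cross_validate <- function(family, cohort, k = 5, seed = 1L, vs = NULL,
                           grouping = "row", mode = "most_likely") {
  key <- normalize_family(family)
  if (is.null(vs)) vs <- attr(cohort, "value_set") %||% "NL"
  vs <- resolve_value_set(vs)
  data <- cohort[cohort$complete %||% rep(TRUE, nrow(cohort)), , drop = FALSE]
  full <- with_scale_scores(data)

  fold <- make_folds(nrow(full), k, seed, grouping = grouping,
                     patient_id = full$patient_id)
  preds <- rep(NA_real_, nrow(full))
  failed <- integer(0)
  fold_metrics <- NULL
  for (f in seq_len(k)) {
    test <- full[fold == f, , drop = FALSE]
    train <- full[fold != f, , drop = FALSE]
    fit <- tryCatch(fit_family(train, key, vs = vs),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", f, " fitting failed: ", conditionMessage(fit),
              call. = FALSE)
      failed <- c(failed, f)
      next
    }
    p <- predict_mapped(fit, test, vs = vs, mode = mode)
    preds[fold == f] <- p
    fm <- compute_metrics(test$utility, p)
    fm <- cbind(data.frame(fold = f), fm)
    fold_metrics <- rbind(fold_metrics, fm)
  }
  ok <- !is.na(preds)
  pooled <- compute_metrics(full$utility[ok], preds[ok])
  structure(list(family = key, label = family_label(key),
                 fold_metrics = fold_metrics, pooled = pooled,
                 predictions = data.frame(observed = full$utility,
                                          predicted = preds, fold = fold),
                 failed_folds = failed, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("5-fold cross-validation:", x$label, "\n")
  print(x$pooled, digits = 3)
  if (length(x$failed_folds))
    cat("failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate fitted mapping models on incomplete questionnaires
#'
#' Scores the incomplete records under the half-completion rule and, for
#' each fitted model, restricts evaluation to the rows where every
#' predictor the model needs is computable; no imputation is performed.
#' Metrics are computed exactly as [compute_metrics()] on the eligible
#' subset, whose size is reported per model.
#'
#' @param cohort Cohort containing incomplete records (`complete ==
#'   FALSE`), e.g. from [generate_cohort()] or
#'   [inject_item_missingness()].
#' @param fits Named list of fitted mapping models (families using scale
#'   scores: 1, 4, 5, 6).
#' @param vs Value set for response-mapping predictions.
#' @param mode Response-mapping scoring mode.
#' @return Data frame: one row per model with `model`, `n_eligible` and
#'   the metric columns.
#' @export
evaluate_incomplete <- function(cohort, fits, vs = NULL,
                                mode = "most_likely") {
  if (is.null(vs)) vs <- attr(cohort, "value_set") %||% "NL"
  vs <- resolve_value_set(vs)
  inc <- cohort[!(cohort$complete %||% rep(TRUE, nrow(cohort))), ,
                drop = FALSE]
  # with no incomplete rows the path degenerates to complete-data evaluation
  if (nrow(inc) == 0) inc <- cohort
  full <- with_scale_scores(inc)
  out <- NULL
  for (nm in names(fits)) {
    need <- required_predictors(fits[[nm]])
    need <- intersect(need, qlq_scale_names())
    elig <- if (length(need))
      rowSums(is.na(full[, need, drop = FALSE])) == 0
    else rep(TRUE, nrow(full))
    if (!any(elig)) stop("no eligible rows for model '", nm, "'",
                         call. = FALSE)
    sub <- full[elig, , drop = FALSE]
    p <- predict_mapped(fits[[nm]], sub, vs = vs, mode = mode)
    m <- compute_metrics(sub$utility, p)
    out <- rbind(out, cbind(data.frame(model = nm, n_eligible = sum(elig)),
                            m))
  }
  rownames(out) <- NULL
  out
}
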