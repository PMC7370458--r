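#' Expected coefficient signs for a mapping family
#'
#' On the utility scale, functional scales and global health carry a
#' positive expected sign (better function, higher utility) and symptom
#' scales a negative one; item terms (and item-level dummies) for
#' `q1`--`q28` are problem-coded and thus negative, while the two
#' global-health items `q29`/`q30` are positive. On the disutility scale
#' (beta family) every expectation is reversed. A fitted coefficient whose
#' sign contradicts this table is "non-logical" and removed by
#' [prune_nonlogical()].
#'
#' @param terms Character vector of predictor terms.
#' @param family Predictor family (`"scale_scores"`, `"continuous_items"`,
#'   `"item_dummies"`).
#' @param scale `"utility"` or `"disutility"`.
#' @return Named numeric vector of expected signs (+1 / -1).
#' @export
sign_convention <- function(terms, family, scale = c("utility", "disutility")) {
  scale <- match.arg(scale)
  sgn <- vapply(terms, function(tm) {
    if (family == "scale_scores") {
      type <- qlq_scales()$type[match(tm, qlq_scales()$scale)]
      if (is.na(type)) stop("unknown scale term '", tm, "'", call. = FALSE)
      if (type == "symptom") -1 else 1
    } else {
      item <- sub("_[0-9]+$", "", tm)
      if (!item %in% qlq_item_names())
        stop("unknown item term '", tm, "'", call. = FALSE)
      if (item %in% c("q29", "q30")) 1 else -1
    }
  }, numeric(1))
  if (scale == "disutility") sgn <- -sgn
  sgn
}

select_worst <- function(ct, alpha) {
  elig <- ct[ct$term != "(Intercept)" & is.finite(ct$p) & ct$p > alpha, ,
             drop = FALSE]
  if (nrow(elig) == 0) return(NULL)
  ord <- order(-elig$p, abs(elig$estimate), elig$term)
  elig[ord[1], ]
}

#' Backward selection at a fixed p-value cut-off
#'
#' Iteratively removes the single least significant predictor (largest
#' p-value above `alpha`; ties broken by smaller absolute coefficient,
#' then name) and refits, until every surviving coefficient satisfies
#' `p <= alpha`. The intercept is never dropped. Intermediate refits reuse
#' the entering model's variance components; the returned model is fully
#' re-estimated. Every removal is appended to the fit's selection history.
#'
#' @param fit A `qolmap_fit` (from [fit_linear()] or [fit_beta()]).
#' @param alpha Retention cut-off (default 0.05).
#' @return The reduced `qolmap_fit`.
#' @export
backward_select <- function(fit, alpha = 0.05) {
  hist <- fit$history
  for (outer in 1:100) {
    changed <- FALSE
    repeat {
      worst <- select_worst(fit$coef_table, alpha)
      if (is.null(worst)) break
      changed <- TRUE
      remaining <- setdiff(fit$terms, worst$term)
      hist <- rbind(hist, data.frame(step = nrow(hist) + 1L,
                                     term = worst$term, reason = "p_value",
                                     value = worst$p,
                                     stringsAsFactors = FALSE))
      if (length(remaining) == 0) {
        warning("all predictors eliminated; returning intercept-only model",
                call. = FALSE)
        fit <- fit$refit(character(0), final = TRUE, history = hist)
        fit$history <- hist
        return(fit)
      }
      fit <- fit$refit(remaining, final = FALSE, history = hist)
    }
    # re-estimate everything for the surviving set; stop when stable
    fit <- fit$refit(fit$terms, final = TRUE, history = hist)
    if (!changed || is.null(select_worst(fit$coef_table, alpha))) break
  }
  fit$history <- hist
  fit
}

#' Remove non-logical (wrong-signed) coefficients
#'
#' After backward selection, any surviving coefficient whose sign
#' contradicts the family's [sign_convention()] (for example a nausea
#' coefficient that would raise utility) is removed; all wrong-signed
#' terms are dropped simultaneously, the model is refit, backward
#' selection is re-run, and the cycle repeats until stable (at most
#' `max_iter` rounds). Every removal is logged with the offending
#' estimate.
#'
#' @param fit A `qolmap_fit`, typically the result of [backward_select()].
#' @param convention Optional named sign vector overriding the default
#'   convention for the fit's family and scale.
#' @param alpha Cut-off used when backward selection is re-run.
#' @param max_iter Maximum prune/re-select rounds.
#' @return The pruned `qolmap_fit`; every surviving coefficient has
#'   `p <= alpha` and a conforming sign.
#' @export
prune_nonlogical <- function(fit, convention = NULL, alpha = 0.05,
                             max_iter = 20) {
  for (iter in seq_len(max_iter)) {
    terms <- fit$terms
    if (length(terms) == 0) break
    sgn <- if (is.null(convention)) {
      sign_convention(terms, fit$model$predictor_family %||% fit$model$family,
                      fit$model$sign_scale %||% "utility")
    } else convention[terms]
    ct <- fit$coef_table[match(terms, fit$coef_table$term), ]
    wrong <- terms[sign(ct$estimate) * sgn < 0]
    if (length(wrong) == 0) break
    hist <- fit$history
    for (tm in wrong)
      hist <- rbind(hist, data.frame(step = nrow(hist) + 1L, term = tm,
                                     reason = "sign",
                                     value = ct$estimate[ct$term == tm],
                                     stringsAsFactors = FALSE))
    keep <- setdiff(terms, wrong)
    fit <- fit$refit(keep, final = TRUE, history = hist)
    fit$history <- hist
    fit <- backward_select(fit, alpha)
  }
  fit
}
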