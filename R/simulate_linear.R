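# Truncated-normal draw on [lo, hi] by inverse-CDF; sd = 0 gives the mean.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

default_item_probs <- function(item) {
  if (item %in% c("q29", "q30"))
    c(0.02, 0.04, 0.08, 0.16, 0.30, 0.25, 0.15)
  else
    c(0.55, 0.30, 0.10, 0.05)
}

draw_scale_covariates <- function(n, covariate_spec) {
  mom <- if (is.null(covariate_spec)) reference_cohort_moments()
         else covariate_spec
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(mom)))
    out[[mom$scale[i]]] <- rtruncnorm01(n, mom$mean[i], mom$sd[i])
  out
}

draw_item_covariates <- function(n) {
  out <- data.frame(row.names = seq_len(n))
  for (it in qlq_item_names()) {
    p <- default_item_probs(it)
    out[[it]] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  out
}

linear_predictor_from_coeffs <- function(covariates, coeffs) {
  terms <- setdiff(names(coeffs), "intercept")
  lp <- rep(if ("intercept" %in% names(coeffs)) coeffs[["intercept"]] else 0,
            nrow(covariates))
  for (tm in terms) {
    if (tm %in% names(covariates)) {
      lp <- lp + coeffs[[tm]] * covariates[[tm]]
    } else if (grepl("^q[0-9]+_[0-9]+$", tm)) {
      item <- sub("_[0-9]+$", "", tm)
      lev <- as.integer(sub("^q[0-9]+_", "", tm))
      if (!item %in% names(covariates))
        stop("unknown coefficient name '", tm, "'", call. = FALSE)
      lp <- lp + coeffs[[tm]] * (covariates[[item]] == lev)
    } else {
      stop("unknown coefficient name '", tm, "'", call. = FALSE)
    }
  }
  lp
}

#' Generate utilities from a known linear mapping model
#'
#' Parameter-recovery harness: draws covariates (scale scores from
#' truncated normals on `[0, 100]` with the reference moments, or items
#' from fixed categorical distributions), then sets
#' `utility = intercept + X beta + patient random intercept + noise`,
#' truncated at 1 (the observed-utility ceiling). Fitting a
#' correctly-specified model to the output recovers the generating
#' coefficients.
#'
#' @param coeffs Named numeric vector: `intercept` plus scale-score names
#'   (`physical`, ..., `financial`), item names (`q1`..`q30`) or item
#'   dummies (`q5_2` = item 5 at level 2).
#' @param n_rows,n_patients Panel dimensions (visits spread evenly).
#' @param noise_sd Residual SD.
#' @param re_sd SD of the patient random intercept.
#' @param covariate_spec Optional data frame `scale`/`mean`/`sd`
#'   overriding the reference covariate moments (scale families only).
#' @param seed Integer seed.
#' @param family `"scale_scores"`, `"items"` or `"item_dummies"` —
#'   which covariates to draw.
#' @param truncate Truncate utilities at 1 (default TRUE).
#' @return Data frame with `patient_id`, `visit`, the covariates and
#'   `utility`.
#' @export
generate_from_linear_model <- function(coeffs, n_rows = 1905L,
                                       n_patients = 473L,
                                       noise_sd = 0.09, re_sd = 0.05,
                                       covariate_spec = NULL, seed = 1L,
                                       family = c("scale_scores", "items",
                                                  "item_dummies"),
                                       truncate = TRUE) {
  family <- match.arg(family)
  coeffs <- unlist(coeffs)
  set.seed(substream_seed(seed, "cohort"))
  covs <- if (family == "scale_scores") draw_scale_covariates(n_rows, covariate_spec)
          else draw_item_covariates(n_rows)
  bad <- setdiff(names(coeffs),
                 c("intercept", names(covs),
                   grep("^q[0-9]+_[0-9]+$", names(coeffs), value = TRUE)))
  if (length(bad))
    stop("unknown coefficient name '", bad[1], "'", call. = FALSE)
  lp <- linear_predictor_from_coeffs(covs, coeffs)

  counts <- balanced_visits(n_patients, n_rows)
  pid <- rep(seq_len(n_patients), counts)
  visit <- unlist(lapply(counts, seq_len), use.names = FALSE)
  b <- stats::rnorm(n_patients, 0, re_sd)
  u <- lp + b[pid] + stats::rnorm(n_rows, 0, noise_sd)
  if (truncate) u <- pmin(u, 1)
  cbind(data.frame(patient_id = pid, visit = visit), covs,
        data.frame(utility = u))
}

#' Generate utilities from a known beta regression on the disutility scale
#'
#' Draws scale-score covariates, computes the logit-scale linear predictor
#' of the disutility model, and draws the transformed disutility from a
#' beta distribution with that mean and fixed precision `phi`
#' (`shape1 = mu * phi`, `shape2 = (1 - mu) * phi`). Utilities are
#' recovered through the inverse of the open-interval transform
#' `(d (N - 1) + 0.5) / N` with `N = n_rows`, so that [fit_beta()] applied
#' to the output reconstructs the generating beta regression exactly in
#' expectation.
#'
#' @param coeffs Named numeric vector on the link (logit) scale:
#'   `intercept` plus scale-score names.
#' @param phi Beta precision parameter.
#' @param n_rows Number of independent rows.
#' @param covariate_spec As in [generate_from_linear_model()].
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `visit`, scale scores and
#'   `utility`.
#' @export
generate_from_beta_model <- function(coeffs, phi = 10, n_rows = 1905L,
                                     covariate_spec = NULL, seed = 1L) {
  coeffs <- unlist(coeffs)
  set.seed(substream_seed(seed, "cohort"))
  covs <- draw_scale_covariates(n_rows, covariate_spec)
  bad <- setdiff(names(coeffs), c("intercept", names(covs)))
  if (length(bad))
    stop("unknown coefficient name '", bad[1], "'", call. = FALSE)
  mu <- stats::plogis(linear_predictor_from_coeffs(covs, coeffs))
  z <- stats::rbeta(n_rows, mu * phi, (1 - mu) * phi)
  u <- pmin(1, 1 - from_open_interval(z, n_rows))
  cbind(data.frame(patient_id = seq_len(n_rows), visit = 1L), covs,
        data.frame(utility = u))
}
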