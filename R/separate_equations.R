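#' Fit the separate-equations mixture model
#'
#' Three-part model for the characteristic shape of EQ-5D utility
#' distributions. A multinomial logistic regression on the candidate scale
#' scores assigns probabilities to three utility classes: `low`
#' (`u < threshold`, by default 0.6 — the region associated with an
#' extreme-problem response on some domain), `mid`
#' (`threshold <= u < 1`) and `one` (`u = 1`, the ceiling). Class-specific
#' random-intercept linear models (fitted as in [fit_linear()], including
#' backward selection and sign pruning) predict utilities within the `low`
#' and `mid` classes; the `one` class predicts utility 1 exactly. The
#' multinomial step itself undergoes no backward selection.
#'
#' @param data Data frame with `utility`, `patient_id` and scale scores.
#' @param candidates Candidate predictors for all three parts (default:
#'   functional plus symptom scale scores).
#' @param threshold Low/mid class boundary on the utility scale.
#' @param select Apply backward selection + sign pruning to the two linear
#'   submodels (default TRUE).
#' @param alpha Selection cut-off.
#' @return A `separate_equations_model` with the class model, the two
#'   submodels and the class counts.
#' @export
fit_separate_equations <- function(data, candidates = NULL, threshold = 0.6,
                                   select = TRUE, alpha = 0.05) {
  if (is.null(candidates))
    candidates <- qlq_scale_names(c("functional", "symptom"))
  u <- data$utility
  cls <- ifelse(u >= 1 - 1e-12, "one", ifelse(u < threshold, "low", "mid"))
  counts <- table(factor(cls, levels = c("low", "mid", "one")))
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop("empty utility class '", empty[1], "' (counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         ")", call. = FALSE)

  df <- data.frame(.cls = factor(cls, levels = c("low", "mid", "one")))
  df$.X <- as.matrix(build_design(data, "scale_scores", candidates))
  mn <- nnet::multinom(.cls ~ .X, data = df, trace = FALSE, maxit = 500)
  cc <- stats::coef(mn)  # rows: mid, one (baseline low); cols: intercept + terms
  colnames(cc) <- c("(Intercept)", sub("^\\.X", "", colnames(cc)[-1]))

  fit_part <- function(part) {
    sub <- data[cls == part, , drop = FALSE]
    f <- fit_linear(sub, "scale_scores", candidates = candidates)
    if (select) f <- prune_nonlogical(backward_select(f, alpha), alpha = alpha)
    f
  }
  low <- fit_part("low")
  mid <- fit_part("mid")

  structure(list(class_model = mn, class_coefficients = cc,
                 candidates = candidates,
                 threshold = threshold, low = low, mid = mid,
                 class_counts = as.vector(counts),
                 family = "separate_equations"),
            class = c("separate_equations_model", "mapping_model"))
}

#' Predict utilities from a separate-equations model
#'
#' Mixture prediction
#' `u = P(low) u_low + P(mid) u_mid + P(one) * 1`, a convex
#' combination of the class-specific predictions.
#'
#' @param model A [fit_separate_equations()] model.
#' @param newdata Data frame with the model's scale-score predictors.
#' @return Numeric vector of predicted utilities.
#' @export
predict_separate_equations <- function(model, newdata) {
  X <- build_design(newdata, "scale_scores", model$candidates)
  if (anyNA(X))
    stop("missing required predictor for class model", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  cc <- model$class_coefficients
  eta <- Xi[, colnames(cc), drop = FALSE] %*% t(cc)  # n x {mid, one}
  den <- 1 + rowSums(exp(eta))
  p_low <- 1 / den
  p_mid <- exp(eta[, "mid"]) / den
  p_one <- exp(eta[, "one"]) / den
  u_low <- predict_linear(model$low, newdata)
  u_mid <- predict_linear(model$mid, newdata)
  as.vector(p_low * u_low + p_mid * u_mid + p_one * 1)
}
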