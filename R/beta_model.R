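#' Map a bounded disutility into the open unit interval (and back)
#'
#' Beta regression cannot model values of exactly 0 or 1, so disutilities
#' on `[0, 1]` are compressed with the standard transform
#' `y' = (y (N - 1) + 0.5) / N`, where `N` is the calibration sample size.
#' `from_open_interval()` is the exact inverse `y = (y' N - 0.5) / (N - 1)`;
#' the round trip is an identity to numerical precision and 0.5 is a fixed
#' point of both directions.
#'
#' @param y Disutility in `[0, 1]` (`to_open_interval`) or transformed
#'   value in `(0, 1)` (`from_open_interval`).
#' @param n Calibration sample size `N` (>= 2).
#' @return Transformed values.
#' @export
to_open_interval <- function(y, n) {
  stopifnot(n >= 2)
  (y * (n - 1) + 0.5) / n
}

#' @rdname to_open_interval
#' @export
from_open_interval <- function(y, n) {
  stopifnot(n >= 2)
  (y * n - 0.5) / (n - 1)
}

#' Fit the beta-regression mapping model on the disutility scale
#'
#' Observed utilities are converted to disutilities `d = 1 - u`;
#' disutilities above 1 (utilities below 0, states worse than dead) are
#' truncated to 1 with a logged count, the result is compressed into the
#' open unit interval with [to_open_interval()] (`N` = training rows), and
#' regressed on the candidate scale scores with a logit-link beta
#' regression (constant precision, estimated by maximum likelihood via
#' `mgcv::gam(family = betar)`). `N` is stored with the model so that
#' prediction applies the matching inverse transform. The returned fit
#' supports [backward_select()] and [prune_nonlogical()] (sign convention
#' reversed, since the outcome is a disutility).
#'
#' @param data Data frame with `utility` and scale-score columns.
#' @param candidates Candidate predictors; defaults to global health plus
#'   the functional and symptom scale scores.
#' @param outcome Utility column name.
#' @return A `qolmap_fit` whose `$model` is the beta mapping model
#'   (link-scale intercept and coefficients, precision `phi`, transform
#'   `N`).
#' @export
fit_beta <- function(data, candidates = NULL, outcome = "utility") {
  if (is.null(candidates))
    candidates <- c("global_health", qlq_scale_names(c("functional", "symptom")))
  u <- data[[outcome]]
  if (is.null(u)) stop("missing outcome column '", outcome, "'", call. = FALSE)
  if (any(u > 1 + 1e-12)) stop("utilities must not exceed 1", call. = FALSE)
  if (nrow(data) < 1) stop("no rows", call. = FALSE)
  ctx <- list(data = data, outcome = outcome, n = nrow(data))
  make_beta_fit(ctx, candidates, history = new_history())
}

make_beta_fit <- function(ctx, terms, history = new_history()) {
  data <- ctx$data
  n <- ctx$n
  d <- 1 - data[[ctx$outcome]]
  n_worse_than_dead <- sum(d > 1)
  if (n_worse_than_dead > 0)
    warning(n_worse_than_dead,
            " disutility value(s) above 1 truncated before the beta fit",
            call. = FALSE)
  z <- to_open_interval(pmin(d, 1), n)
  X <- build_design(data, "scale_scores", terms)
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in candidate predictor(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.z = z)
  fml <- if (ncol(X) > 0) { df$.X <- X; .z ~ .X } else .z ~ 1
  g <- mgcv::gam(fml, data = df, family = mgcv::betar(link = "logit"),
                 method = "REML")
  sm <- summary(g)
  pt <- sm$p.table
  rn <- rownames(pt)
  rn[rn == "(Intercept)"] <- "(Intercept)"
  rn <- sub("^\\.X", "", rn)
  ct <- data.frame(term = rn, estimate = pt[, 1], se = pt[, 2],
                   stat = pt[, 3], p = pt[, 4],
                   conf_low = pt[, 1] - 1.96 * pt[, 2],
                   conf_high = pt[, 1] + 1.96 * pt[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  beta <- stats::coef(g)
  names(beta) <- sub("^\\.X", "", names(beta))
  coefs <- beta[setdiff(names(beta), "(Intercept)")]
  model <- list(
    family = "beta", predictor_family = "scale_scores",
    sign_scale = "disutility",
    intercept = unname(beta[["(Intercept)"]]),
    coefficients = coefs,
    phi = g$family$getTheta(TRUE),
    link = "logit", transform_n = n,
    n = n, n_truncated = n_worse_than_dead
  )
  class(model) <- "mapping_model"
  fit <- list(model = model, coef_table = ct, terms = terms,
              history = history, ctx = ctx)
  fit$refit <- function(new_terms, final = TRUE, history = fit$history) {
    make_beta_fit(ctx, new_terms, history = history)
  }
  class(fit) <- c("qolmap_beta_fit", "qolmap_fit")
  fit
}

#' Predict utilities from a fitted beta mapping model
#'
#' Applies the logit-link mean to the linear predictor and maps it back to
#' the utility scale through the inverse open-interval transform with the
#' training `N`. Predictions therefore lie strictly inside the image of the
#' inverse transform: strictly below 1, and never below
#' `1 - (N - 0.5)/(N - 1)`-scaled support.
#'
#' @param model A `qolmap_fit` from [fit_beta()] or its `$model`.
#' @param newdata Data frame with the model's scale-score predictors.
#' @return Numeric vector of predicted utilities.
#' @export
predict_beta <- function(model, newdata) {
  if (inherits(model, "qolmap_fit")) model <- model$model
  terms <- names(model$coefficients)
  X <- build_design(newdata, "scale_scores", terms)
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing required predictor '", bad[1], "'", call. = FALSE)
  }
  lp <- rep(model$intercept, nrow(newdata))
  if (length(terms)) lp <- lp + as.vector(X %*% model$coefficients)
  mu <- stats::plogis(lp)
  1 - from_open_interval(mu, model$transform_n)
}
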