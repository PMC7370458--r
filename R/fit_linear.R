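# ---- design matrices ---------------------------------------------------

#' Default candidate predictor sets for the linear mapping families
#'
#' `scale_scores`: the five functional and nine symptom scale scores
#' (global health excluded, as in the scale-score mapping family);
#' `continuous_items`: the 30 items as integers; `item_dummies`: one dummy
#' per item level above the reference level 1, restricted to levels
#' observed in `data`.
#'
#' @param data Data frame (needed for `item_dummies` to enumerate observed
#'   levels; optional otherwise).
#' @param family Mapping family.
#' @return Character vector of candidate term names.
#' @export
default_candidates <- function(family, data = NULL) {
  switch(family,
    scale_scores = qlq_scale_names(c("functional", "symptom")),
    continuous_items = qlq_item_names(),
    item_dummies = {
      if (is.null(data)) stop("data needed to enumerate dummy levels")
      unlist(lapply(qlq_item_names(), function(it) {
        lev <- sort(unique(data[[it]]))
        lev <- lev[lev > 1 & !is.na(lev)]
        if (length(lev)) paste0(it, "_", lev) else character(0)
      }))
    },
    stop("unknown family '", family, "'", call. = FALSE))
}

# Build the n x p predictor matrix for the given terms (no intercept).
build_design <- function(data, family, terms) {
  n <- nrow(data)
  if (length(terms) == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  cols <- lapply(terms, function(tm) {
    if (family == "item_dummies" && grepl("^q[0-9]+_[0-9]+$", tm)) {
      item <- sub("_[0-9]+$", "", tm)
      lev <- as.integer(sub("^q[0-9]+_", "", tm))
      v <- data[[item]]
      if (is.null(v)) stop("missing required predictor '", item, "'",
                           call. = FALSE)
      as.numeric(v == lev)
    } else {
      v <- data[[tm]]
      if (is.null(v)) stop("missing required predictor '", tm, "'",
                           call. = FALSE)
      as.numeric(v)
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# Drop zero-variance and aliased columns, with a logged warning.
drop_aliased <- function(X) {
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 1) {
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1) {
      piv <- qrX$pivot[seq_len(qrX$rank)]
      alias <- setdiff(seq_len(ncol(X) + 1), piv) - 1L
      alias <- alias[alias > 0]
      dropped <- c(dropped, colnames(X)[alias])
      X <- X[, -alias, drop = FALSE]
    }
  }
  if (length(dropped))
    warning("dropped singular predictor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  X
}

# ---- random-intercept GLS with cluster-robust sandwich ----------------

# Variance components of the random-intercept model by maximum likelihood.
estimate_varcomp <- function(X, y, cluster) {
  df <- data.frame(.y = y, .cl = cluster)
  fml <- if (ncol(X) > 0) {
    df$.X <- X
    .y ~ .X + (1 | .cl)
  } else .y ~ 1 + (1 | .cl)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (is.null(fit)) return(list(s2b = 0, s2e = 1))
  vc <- lme4::VarCorr(fit)
  s2b <- as.numeric(vc$.cl[1, 1])
  s2e <- stats::sigma(fit)^2
  if (!is.finite(s2b) || s2b < 0) s2b <- 0
  if (!is.finite(s2e) || s2e <= 0) s2e <- 1
  list(s2b = s2b, s2e = s2e)
}

# GLS estimate via quasi-demeaning, plus the cluster-robust (CR1) sandwich
# computed with the working covariance V_g = s2b J + s2e I (Woodbury).
re_gls_fit <- function(X, y, cluster, s2b, s2e) {
  Xi <- cbind(`(Intercept)` = 1, X)
  cl <- as.factor(cluster)
  m <- as.vector(table(cl))
  G <- nlevels(cl)

  if (G < 2 || s2b <= 0) {
    lambda <- rep(0, G)
  } else {
    lambda <- 1 - sqrt(s2e / (s2e + m * s2b))
  }
  idx <- as.integer(cl)
  ybar <- rowsum(y, cl) / m
  Xbar <- rowsum(Xi, cl) / m
  yt <- y - lambda[idx] * ybar[idx]
  Xt <- Xi - lambda[idx] * Xbar[idx, , drop = FALSE]
  fit <- stats::lm.fit(Xt, yt)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  e <- as.vector(y - Xi %*% beta)

  # X' V^{-1} X and per-cluster X_g' V_g^{-1} e_g (scale 1/s2e cancels in
  # the sandwich but is kept for interpretability)
  c1 <- if (G < 2 || s2b <= 0) rep(0, G) else s2b / (s2e + m * s2b)
  S <- rowsum(Xi, cl)                     # per-cluster column sums
  A <- (crossprod(Xi) - crossprod(S * sqrt(c1))) / s2e
  U <- rowsum(Xi * e, cl)
  se_g <- as.vector(rowsum(e, cl))
  Umod <- (U - (c1 * se_g) * S) / s2e
  meat <- crossprod(Umod)
  Ainv <- tryCatch(solve(A), error = function(err) MASS::ginv(A))
  corr <- if (G > 1) G / (G - 1) else 1
  V <- corr * Ainv %*% meat %*% Ainv
  dimnames(V) <- list(colnames(Xi), colnames(Xi))
  list(beta = beta, vcov = V, resid = e, df = max(G - 1, 1),
       n = length(y), G = G)
}

coef_table_from <- function(beta, V, df) {
  se <- sqrt(pmax(diag(V), 0))
  stat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p <- 2 * stats::pt(-abs(stat), df)
  q <- stats::qt(0.975, df)
  data.frame(term = names(beta), estimate = unname(beta), se = unname(se),
             stat = unname(stat), p = unname(p),
             conf_low = unname(beta - q * se),
             conf_high = unname(beta + q * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

new_history <- function() {
  data.frame(step = integer(0), term = character(0), reason = character(0),
             value = numeric(0), stringsAsFactors = FALSE)
}

#' Fit a random-intercept linear mapping model
#'
#' Regresses the observed utility on the family's candidate predictors with
#' a patient-level random intercept. Variance components are estimated by
#' maximum likelihood (lme4); the fixed effects are the implied GLS
#' estimates, and inference uses a cluster-robust sandwich covariance over
#' patients (t statistics on `clusters - 1` degrees of freedom), so that
#' repeated questionnaires from one patient do not overstate precision.
#' Zero-variance or aliased candidates are dropped with a warning before
#' fitting. With fewer than two clusters (or `use_re = FALSE`) the fit
#' reduces to ordinary least squares.
#'
#' @param data Data frame with the outcome, predictors and cluster key.
#' @param family `"scale_scores"`, `"continuous_items"` or
#'   `"item_dummies"`.
#' @param candidates Candidate terms (default [default_candidates()]).
#' @param outcome,cluster Column names of the outcome and the cluster key.
#' @param use_re Set `FALSE` for plain OLS with cluster-robust errors.
#' @return A `qolmap_fit`: `model` (intercept, coefficients, family,
#'   variance components), `coef_table` (estimate, robust SE, t, p, 95%
#'   CI), `history` (selection log), and a `refit` closure used by
#'   [backward_select()] and [prune_nonlogical()].
#' @export
fit_linear <- function(data, family = c("scale_scores", "continuous_items",
                                        "item_dummies"),
                       candidates = NULL, outcome = "utility",
                       cluster = "patient_id", use_re = TRUE) {
  family <- match.arg(family)
  if (is.null(candidates)) candidates <- default_candidates(family, data)
  y <- data[[outcome]]
  if (is.null(y)) stop("missing outcome column '", outcome, "'", call. = FALSE)
  cl <- data[[cluster]]
  if (is.null(cl)) stop("missing cluster column '", cluster, "'",
                        call. = FALSE)
  X0 <- build_design(data, family, candidates)
  if (anyNA(X0)) {
    bad <- colnames(X0)[colSums(is.na(X0)) > 0]
    stop("missing values in candidate predictor(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  X0 <- drop_aliased(X0)

  ctx <- list(data = data, family = family, outcome = outcome,
              cluster = cluster, use_re = use_re,
              sign_scale = "utility")
  make_fit(ctx, colnames(X0), varcomp = NULL, history = new_history())
}

# Internal constructor shared by fit_linear and refits.
make_fit <- function(ctx, terms, varcomp = NULL, history = new_history()) {
  y <- ctx$data[[ctx$outcome]]
  cl <- ctx$data[[ctx$cluster]]
  X <- build_design(ctx$data, ctx$family, terms)
  use_re <- ctx$use_re && length(unique(cl)) >= 2
  if (is.null(varcomp)) {
    varcomp <- if (use_re) estimate_varcomp(X, y, cl) else list(s2b = 0, s2e = 1)
  }
  if (!use_re) varcomp$s2b <- 0
  res <- re_gls_fit(X, y, cl, varcomp$s2b, varcomp$s2e)
  ct <- coef_table_from(res$beta, res$vcov, res$df)
  coefs <- res$beta[setdiff(names(res$beta), "(Intercept)")]
  model <- list(
    family = ctx$family, predictor_family = ctx$family,
    sign_scale = ctx$sign_scale,
    intercept = unname(res$beta[["(Intercept)"]]),
    coefficients = coefs,
    sigma_b = sqrt(varcomp$s2b), sigma_e = sqrt(varcomp$s2e),
    estimator = if (use_re) "re_cluster_robust" else "ols",
    n = res$n, n_clusters = res$G
  )
  class(model) <- "mapping_model"
  fit <- list(model = model, coef_table = ct, terms = terms,
              history = history, varcomp = varcomp, ctx = ctx)
  fit$refit <- function(new_terms, final = TRUE, history = fit$history) {
    make_fit(ctx, new_terms, varcomp = if (final) NULL else varcomp,
             history = history)
  }
  class(fit) <- c("qolmap_linear_fit", "qolmap_fit")
  fit
}

#' @export
print.qolmap_fit <- function(x, ...) {
  cat("Mapping model fit (", x$model$family, ", ",
      x$model$estimator %||% "ml", ")\n", sep = "")
  print(x$coef_table, digits = 4)
  if (nrow(x$history))
    cat(nrow(x$history), "term(s) removed during selection\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict utilities from a linear mapping model
#'
#' `utility = intercept + sum(coefficient * predictor)`. Predictions are
#' deliberately not clipped: linear mapping algorithms can predict outside
#' the observed utility range.
#'
#' @param model A `qolmap_fit`, its `$model`, or a loaded coefficient set
#'   (see [load_mapping_model()]).
#' @param newdata Data frame holding every predictor the model names
#'   (scale scores or items); a missing or `NA` predictor is an error
#'   naming the offender.
#' @return Numeric vector of predicted utilities.
#' @export
predict_linear <- function(model, newdata) {
  if (inherits(model, "qolmap_fit")) model <- model$model
  terms <- names(model$coefficients)
  X <- build_design(newdata, model$predictor_family %||% model$family, terms)
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing required predictor '", bad[1], "'", call. = FALSE)
  }
  lp <- rep(model$intercept, nrow(newdata))
  if (length(terms)) lp <- lp + as.vector(X %*% model$coefficients)
  lp
}
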