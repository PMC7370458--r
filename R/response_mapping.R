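#' Fit the response-mapping family: one ordered logit per EQ-5D domain
#'
#' For each of the five EQ-5D-3L domains, fits a proportional-odds
#' (ordered logit) model of the domain level on the five QLQ-C30
#' functional scale scores (MASS::polr). No backward selection is applied
#' to this family. The fitted latent predictor is reported in the
#' "level-anchored" parameterisation: `L = x'beta - zeta_1`, with the
#' upper threshold offset `kappa = zeta_2 - zeta_1`, so that
#' `P(level 1) = 1 / (1 + exp(L))` and
#' `P(level <= 2) = 1 / (1 + exp(L - kappa))`.
#'
#' @param data Data frame with the five domain level columns and the five
#'   functional scale scores.
#' @param predictors Predictor names (default: the functional scales).
#' @return A `response_mapping_model`: per-domain coefficient vectors and
#'   thresholds, with strictly increasing `zeta`.
#' @export
fit_response_mapping <- function(data, predictors = qlq_scale_names("functional")) {
  doms <- eq5d_domains()
  X <- data[, predictors, drop = FALSE]
  if (anyNA(X))
    stop("missing values in predictor(s)", call. = FALSE)
  models <- list()
  for (d in doms) {
    lev <- data[[d]]
    obs <- sort(unique(lev))
    if (length(obs) < 2)
      stop("degenerate domain '", d, "': only level ",
           paste(obs, collapse = ","), " observed", call. = FALSE)
    df <- data.frame(.y = factor(lev, levels = 1:3))
    df <- droplevels(df)
    df$.X <- as.matrix(X)
    if (nlevels(df$.y) >= 3) {
      fit <- MASS::polr(.y ~ .X, data = df, method = "logistic", Hess = TRUE)
      beta <- stats::coef(fit)
      zeta <- unname(fit$zeta)
      se <- sqrt(diag(stats::vcov(fit)))[seq_along(beta)]
    } else {
      # only two levels observed: ordered logit reduces to logistic
      # regression with a single threshold
      fit <- stats::glm(I(.y == levels(.y)[2]) ~ .X, data = df,
                        family = stats::binomial())
      cf <- stats::coef(fit)
      beta <- cf[-1]
      zeta <- -unname(cf[1])
      se <- sqrt(diag(stats::vcov(fit)))[-1]
    }
    names(beta) <- sub("^\\.X", "", names(beta))
    names(se) <- names(beta)
    models[[d]] <- list(
      coefficients = beta,
      zeta = zeta,
      levels = as.integer(levels(df$.y)),
      se = se
    )
  }
  structure(list(domains = models, predictors = predictors,
                 family = "response_mapping"),
            class = c("response_mapping_model", "mapping_model"))
}

#' Level probabilities of one EQ-5D domain under an ordered logit
#'
#' With latent predictor `L` and threshold offset `kappa`:
#' `Prob1 = 1/(1 + e^L)`, `Prob2 = 1/(1 + e^(L - kappa)) - Prob1`,
#' `Prob3 = 1 - Prob1 - Prob2`. Probabilities are returned per row and
#' always sum to one.
#'
#' @param domain_model One element of a [fit_response_mapping()] model
#'   (fields `coefficients`, `zeta`), or a list with those fields.
#' @param scores Data frame (or named vector) of the model's predictors.
#' @return Matrix with columns `p1`, `p2`, `p3`.
#' @export
domain_level_probs <- function(domain_model, scores) {
  if (is.null(dim(scores))) scores <- as.data.frame(as.list(scores))
  beta <- domain_model$coefficients
  X <- as.matrix(scores[, names(beta), drop = FALSE])
  eta <- as.vector(X %*% beta)
  zeta <- domain_model$zeta
  L <- eta - zeta[1]
  p1 <- stats::plogis(-L)          # 1/(1 + e^L)
  if (length(zeta) >= 2) {
    kappa <- zeta[2] - zeta[1]
    p12 <- stats::plogis(-(L - kappa))
  } else {
    p12 <- rep(1, length(L))       # only two levels observed in training
  }
  p2 <- p12 - p1
  p3 <- 1 - p12
  cbind(p1 = p1, p2 = p2, p3 = p3)
}

#' Predict utilities by response mapping
#'
#' Two scoring modes. `"most_likely"`: for each domain take the level with
#' the highest predicted probability (ties resolved to the lower, i.e.
#' better, level) and score the resulting 5-domain state with the value
#' set. `"expected"`: the expected utility under the predicted level
#' probabilities, `constant - sum_d sum_l p_dl * decrement_dl`, with extra
#' terms (any-deviation and any-level-3 constants) evaluated under
#' independence of domains given the scores. The chosen mode is recorded
#' as an attribute of the result.
#'
#' @param model A [fit_response_mapping()] model.
#' @param scores Data frame of functional scale scores.
#' @param vs An `eq5d_value_set`.
#' @param mode `"most_likely"` (default) or `"expected"`.
#' @return Numeric vector of utilities with attributes `mode` and
#'   `tariff`.
#' @export
predict_response_mapping <- function(model, scores, vs,
                                     mode = c("most_likely", "expected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vs, "eq5d_value_set"))
  doms <- eq5d_domains()
  probs <- lapply(doms, function(d) {
    p <- domain_level_probs(model$domains[[d]], scores)
    # map onto absolute levels 1..3 when a training level was unobserved
    lev <- model$domains[[d]]$levels
    full <- matrix(0, nrow = nrow(p), ncol = 3,
                   dimnames = list(NULL, c("p1", "p2", "p3")))
    full[, lev[1]] <- p[, 1]
    if (length(lev) >= 2) full[, lev[2]] <- p[, 2]
    if (length(lev) >= 3) full[, lev[3]] <- p[, 3]
    full
  })
  names(probs) <- doms
  n <- nrow(probs[[1]])

  if (mode == "most_likely") {
    state <- data.frame(row.names = seq_len(n))
    for (d in doms)
      state[[d]] <- max.col(probs[[d]], ties.method = "first")
    u <- as.numeric(eq5d_utility(state, vs))
  } else {
    u <- rep(vs$constant, n)
    for (d in doms)
      u <- u - as.vector(probs[[d]] %*% vs$decrements[d, ])
    for (e in vs$extras) {
      p_none <- rep(1, n)
      for (d in doms) {
        p_none <- p_none * switch(e$predicate,
          any_level_gt1 = probs[[d]][, 1],
          any_level_3   = 1 - probs[[d]][, 3])
      }
      u <- u - e$value * (1 - p_none)
    }
  }
  attr(u, "mode") <- mode
  attr(u, "tariff") <- vs$name
  u
}
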