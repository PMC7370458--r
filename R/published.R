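#' Save a fitted mapping model as a portable coefficient file
#'
#' Writes a JSON coefficient file with schema
#' `{name, family, tariff, inputs, intercept, coefficients, thresholds,
#' transform, mode}`. Linear families store intercept and coefficient map;
#' the beta family additionally stores the precision and the
#' open-interval transform `N`; the response-mapping family stores the
#' per-domain coefficient sets and thresholds. Coefficients are stored at
#' full precision, so a save/load round trip reproduces in-memory
#' predictions exactly.
#'
#' @param fit A `qolmap_fit`, a bare `mapping_model`, or a
#'   `response_mapping_model`.
#' @param path Output path.
#' @param name Model name recorded in the file.
#' @param tariff Tariff tag (informational; response-mapping models are
#'   tariff-independent until scoring).
#' @param mode Scoring mode recorded for response-mapping models.
#' @export
save_mapping_model <- function(fit, path, name = "mapping_model",
                               tariff = NA_character_,
                               mode = "most_likely") {
  model <- if (inherits(fit, "qolmap_fit")) fit$model else fit
  js <- if (inherits(model, "separate_equations_model")) {
    list(name = name, family = "separate_equations", tariff = tariff,
         inputs = model$candidates, threshold = model$threshold,
         class_coefficients = apply(model$class_coefficients, 1, as.list,
                                    simplify = FALSE),
         class_terms = colnames(model$class_coefficients),
         low = list(intercept = model$low$model$intercept,
                    coefficients = as.list(model$low$model$coefficients)),
         mid = list(intercept = model$mid$model$intercept,
                    coefficients = as.list(model$mid$model$coefficients)))
  } else if (inherits(model, "response_mapping_model")) {
    list(name = name, family = "response_mapping", tariff = tariff,
         inputs = model$predictors, mode = mode,
         domains = lapply(model$domains, function(d)
           list(coefficients = as.list(d$coefficients),
                zeta = d$zeta, levels = d$levels)))
  } else if (identical(model$family, "beta")) {
    list(name = name, family = "beta", tariff = tariff,
         inputs = names(model$coefficients),
         intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         precision = model$phi, link = model$link,
         transform = list(N = model$transform_n))
  } else {
    fam <- switch(model$family,
                  scale_scores = "linear_scale_scores",
                  continuous_items = "linear_items",
                  item_dummies = "linear_item_dummies",
                  model$family)
    list(name = name, family = fam, tariff = tariff,
         inputs = names(model$coefficients),
         intercept = model$intercept,
         coefficients = as.list(model$coefficients))
  }
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a mapping-model coefficient file
#'
#' Reads the JSON schema written by [save_mapping_model()] (also the
#' schema used for user-supplied published algorithms). The returned
#' object predicts through [predict_mapped()].
#'
#' @param path Path to a coefficient JSON file.
#' @return A `mapping_model` (or `response_mapping_model`).
#' @export
load_mapping_model <- function(path) {
  if (!file.exists(path))
    stop("coefficient file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  fam <- js$family
  known <- c("linear_scale_scores", "linear_items", "linear_item_dummies",
             "beta", "response_mapping", "separate_equations")
  if (is.null(fam) || !fam %in% known)
    stop("coefficient file schema error: unknown family tag '",
         if (is.null(fam)) "<missing>" else fam, "'", call. = FALSE)
  if (fam == "separate_equations") {
    cc <- do.call(rbind, lapply(js$class_coefficients, unlist))
    rownames(cc) <- c("mid", "one")
    colnames(cc) <- as.character(unlist(js$class_terms))
    sub_model <- function(part, nm) {
      m <- list(family = "scale_scores", predictor_family = "scale_scores",
                sign_scale = "utility",
                intercept = as.numeric(part$intercept),
                coefficients = unlist(part$coefficients), name = nm)
      class(m) <- "mapping_model"
      m
    }
    return(structure(list(class_coefficients = cc,
                          candidates = as.character(unlist(js$inputs)),
                          threshold = as.numeric(js$threshold),
                          low = sub_model(js$low, "low"),
                          mid = sub_model(js$mid, "mid"),
                          family = "separate_equations", name = js$name),
                     class = c("separate_equations_model", "mapping_model")))
  }
  if (fam == "response_mapping") {
    doms <- lapply(js$domains, function(d)
      list(coefficients = unlist(d$coefficients),
           zeta = as.numeric(unlist(d$zeta)),
           levels = as.integer(unlist(d$levels))))
    return(structure(list(domains = doms,
                          predictors = as.character(unlist(js$inputs)),
                          family = "response_mapping",
                          mode = js$mode %||% "most_likely",
                          name = js$name),
                     class = c("response_mapping_model", "mapping_model")))
  }
  pred_fam <- switch(fam,
                     linear_scale_scores = "scale_scores",
                     linear_items = "continuous_items",
                     linear_item_dummies = "item_dummies",
                     beta = "scale_scores")
  model <- list(
    family = if (fam == "beta") "beta" else pred_fam,
    predictor_family = pred_fam,
    sign_scale = if (fam == "beta") "disutility" else "utility",
    intercept = as.numeric(js$intercept),
    coefficients = unlist(js$coefficients),
    name = js$name, tariff = js$tariff
  )
  if (fam == "beta") {
    model$phi <- as.numeric(js$precision)
    model$link <- js$link %||% "logit"
    model$transform_n <- as.numeric(js$transform$N)
  }
  class(model) <- "mapping_model"
  model
}

#' Predict utilities with any mapping model
#'
#' Dispatches on the model family: linear families through
#' [predict_linear()], beta through [predict_beta()], response mapping
#' through [predict_response_mapping()] (which additionally needs a value
#' set), separate equations through [predict_separate_equations()].
#'
#' @param model A fitted or loaded mapping model.
#' @param newdata Data frame with the required predictors.
#' @param vs Value set (response mapping only).
#' @param mode Scoring mode (response mapping only).
#' @return Numeric vector of predicted utilities.
#' @export
predict_mapped <- function(model, newdata, vs = NULL, mode = NULL) {
  if (inherits(model, "qolmap_fit")) model <- model$model
  if (inherits(model, "response_mapping_model")) {
    if (is.null(vs)) stop("response mapping needs a value set", call. = FALSE)
    return(predict_response_mapping(model, newdata, vs,
                                    mode = mode %||% model$mode %||%
                                      "most_likely"))
  }
  if (inherits(model, "separate_equations_model"))
    return(predict_separate_equations(model, newdata))
  if (identical(model$family, "beta")) return(predict_beta(model, newdata))
  predict_linear(model, newdata)
}

#' Apply a published mapping algorithm from a coefficient file
#'
#' Loads the file, checks that the data provide the family's inputs, and
#' dispatches to the matching prediction routine. The package ships one
#' published algorithm, `published_algorithm_path()`: a linear model on
#' the QLQ-C30 scale scores estimated on 1905 questionnaires from a
#' metastatic colorectal cancer cohort (Dutch tariff).
#'
#' @param path Coefficient JSON file.
#' @param data Data frame of scale scores or items (a scored or raw,
#'   possibly [binarize_v3_items()]-converted, questionnaire table).
#' @param vs,mode Passed through for response-mapping files.
#' @return Numeric vector of predicted utilities.
#' @export
apply_published <- function(path, data, vs = NULL, mode = NULL) {
  model <- load_mapping_model(path)
  predict_mapped(model, data, vs = vs, mode = mode)
}

#' @rdname apply_published
#' @export
published_algorithm_path <- function() {
  system.file("extdata", "model1_mcrc_scale_scores_nl.json",
              package = "qolmap")
}
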