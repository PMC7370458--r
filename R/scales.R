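#' Scale structure of the EORTC QLQ-C30 version 3.0
#'
#' Returns the declarative item-to-scale assignment used by
#' [score_qlqc30()]: five functional scales, global health status, three
#' multi-item symptom scales and six single-item symptoms. Items `q1`--`q28`
#' are answered on a 4-point ordinal scale ("not at all" = 1 to
#' "very much" = 4); the two global-health items `q29`/`q30` on a 7-point
#' scale ("very poor" = 1 to "excellent" = 7).
#'
#' @return A data frame with one row per scale: `scale` (key used as column
#'   name in scored output), `type` (`"functional"`, `"global"` or
#'   `"symptom"`), `items` (list column of item names) and `range` (item
#'   range: 3 for 4-point items, 6 for 7-point items).
#' @export
#' @examples
#' qlq_scales()
qlq_scales <- function() {
  s <- function(scale, type, items, range = 3L)
    data.frame(scale = scale, type = type, range = range,
               items = I(list(items)), stringsAsFactors = FALSE)
  rbind(
    s("physical",        "functional", paste0("q", 1:5)),
    s("role",            "functional", paste0("q", 6:7)),
    s("emotional",       "functional", paste0("q", 21:24)),
    s("cognitive",       "functional", paste0("q", c(20, 25))),
    s("social",          "functional", paste0("q", 26:27)),
    s("global_health",   "global",     paste0("q", 29:30), 6L),
    s("fatigue",         "symptom",    paste0("q", c(10, 12, 18))),
    s("nausea_vomiting", "symptom",    paste0("q", 14:15)),
    s("pain",            "symptom",    paste0("q", c(9, 19))),
    s("dyspnea",         "symptom",    "q8"),
    s("insomnia",        "symptom",    "q11"),
    s("appetite_loss",   "symptom",    "q13"),
    s("constipation",    "symptom",    "q16"),
    s("diarrhea",        "symptom",    "q17"),
    s("financial",       "symptom",    "q28")
  )
}

#' Names of the 15 QLQ-C30 scale scores
#'
#' @param type Optional filter: `"functional"`, `"global"` or `"symptom"`.
#' @return Character vector of scale keys.
#' @export
qlq_scale_names <- function(type = NULL) {
  tab <- qlq_scales()
  if (!is.null(type)) tab <- tab[tab$type %in% type, ]
  tab$scale
}

qlq_item_names <- function() paste0("q", 1:30)

qlq_item_max <- function() {
  mx <- rep(4L, 30)
  mx[29:30] <- 7L
  names(mx) <- qlq_item_names()
  mx
}

check_qlq_items <- function(data) {
  mx <- qlq_item_max()
  for (it in qlq_item_names()) {
    if (!it %in% names(data))
      stop("missing QLQ-C30 item column '", it, "'", call. = FALSE)
    v <- data[[it]]
    bad <- !is.na(v) & (v < 1 | v > mx[[it]] | v != round(v))
    if (any(bad))
      stop("item '", it, "' outside declared range 1-", mx[[it]],
           " in row(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Score QLQ-C30 v3.0 questionnaires
#'
#' Computes the 15 scale scores from raw item responses following the EORTC
#' scoring conventions. For each scale the raw score is the mean of the
#' answered items; functional scales are scored
#' `(1 - (RS - 1)/range) * 100` (higher = better functioning), symptom
#' scales and global health `((RS - 1)/range) * 100` (higher = worse
#' symptoms / better global health). A scale is missing unless at least
#' half of its items (rounded up) are answered (half-completion rule).
#'
#' @param data Data frame with item columns `q1`..`q30` (integer levels,
#'   `NA` = missing). Identifier columns `patient_id` and `visit` are
#'   carried through when present.
#' @return Data frame with the carried identifier columns and one column
#'   per scale score in `[0, 100]` (`NA` where the half-completion rule
#'   fails).
#' @export
#' @examples
#' rec <- as.data.frame(as.list(stats::setNames(rep(1, 30), paste0("q", 1:30))))
#' rec$q29 <- rec$q30 <- 7
#' score_qlqc30(rec)$physical  # 100: best possible responses
score_qlqc30 <- function(data) {
  data <- as.data.frame(data)
  check_qlq_items(data)
  tab <- qlq_scales()
  ids <- intersect(c("patient_id", "visit"), names(data))
  out <- data[, ids, drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    items <- as.matrix(data[, tab$items[[i]], drop = FALSE])
    n_items <- ncol(items)
    answered <- rowSums(!is.na(items))
    rs <- rowMeans(items, na.rm = TRUE)
    rs[answered < ceiling(n_items / 2)] <- NA_real_
    rng <- tab$range[i]
    score <- if (tab$type[i] == "functional") {
      (1 - (rs - 1) / rng) * 100
    } else {
      ((rs - 1) / rng) * 100
    }
    out[[tab$scale[i]]] <- score
  }
  rownames(out) <- NULL
  out
}

#' Collapse the first five QLQ-C30 items to the version 2 binary coding
#'
#' QLQ-C30 version 2 asked items 1--5 as yes/no questions; published
#' algorithms estimated on version 2 data therefore expect binary inputs.
#' Maps level 1 ("not at all") to 1 ("no") and levels 2--4 to 2 ("yes");
#' missing values are preserved.
#'
#' @param data Data frame with columns `q1`..`q5` (other columns are
#'   carried through unchanged).
#' @return `data` with `q1`..`q5` recoded to `{1, 2}`.
#' @export
binarize_v3_items <- function(data) {
  data <- as.data.frame(data)
  mx <- qlq_item_max()
  for (it in paste0("q", 1:5)) {
    if (!it %in% names(data))
      stop("missing item column '", it, "'", call. = FALSE)
    v <- data[[it]]
    bad <- !is.na(v) & (v < 1 | v > mx[[it]])
    if (any(bad))
      stop("item '", it, "' outside declared range 1-", mx[[it]], call. = FALSE)
    data[[it]] <- ifelse(is.na(v), NA_real_, ifelse(v >= 2, 2, 1))
  }
  data
}
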