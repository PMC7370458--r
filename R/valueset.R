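eq5d_domains <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort",
    "anxiety_depression")
}

#' Construct an EQ-5D-3L value set (tariff)
#'
#' A value set maps a 5-domain level vector to a utility:
#' `utility = constant - sum(level decrements) - sum(triggered extras)`.
#' Extras are `(predicate, value)` pairs; supported predicates are
#' `"any_level_gt1"` (any domain above level 1, the usual "any deviation"
#' constant) and `"any_level_3"` (any domain at level 3, the N3 term).
#' The full-health state 1-1-1-1-1 always scores `constant` (extras never
#' trigger there), and level-1 decrements are zero by construction.
#'
#' @param name Tariff name (e.g. `"NL"`).
#' @param constant Full-health utility, conventionally 1.
#' @param decrements Named list (one entry per domain) of named numeric
#'   vectors giving the decrement for levels `"2"` and `"3"`.
#' @param extras List of `list(predicate =, value =)` entries.
#' @return An object of class `eq5d_value_set`.
#' @export
#' @examples
#' toy <- value_set("toy", 1,
#'   decrements = stats::setNames(
#'     rep(list(c(`2` = 0.1, `3` = 0.3)), 5),
#'     c("mobility", "self_care", "usual_activities",
#'       "pain_discomfort", "anxiety_depression")))
#' eq5d_utility(data.frame(mobility = 2, self_care = 1,
#'   usual_activities = 3, pain_discomfort = 1, anxiety_depression = 1), toy)
value_set <- function(name, constant = 1, decrements, extras = list()) {
  doms <- eq5d_domains()
  if (!all(doms %in% names(decrements)))
    stop("malformed decrement table: missing domain(s) ",
         paste(setdiff(doms, names(decrements)), collapse = ", "),
         call. = FALSE)
  dec <- matrix(0, nrow = 5, ncol = 3, dimnames = list(doms, c("1", "2", "3")))
  for (d in doms) {
    v <- decrements[[d]]
    if (!is.numeric(v) || is.null(names(v)))
      stop("malformed decrement table for domain '", d, "'", call. = FALSE)
    if ("1" %in% names(v) && any(v[["1"]] != 0))
      stop("level-1 decrements must be zero (domain '", d, "')", call. = FALSE)
    for (l in intersect(names(v), c("2", "3"))) dec[d, l] <- v[[l]]
  }
  ok_pred <- c("any_level_gt1", "any_level_3")
  for (e in extras) {
    if (!is.list(e) || !all(c("predicate", "value") %in% names(e)) ||
        !e$predicate %in% ok_pred)
      stop("malformed extra term; predicate must be one of ",
           paste(ok_pred, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, constant = constant, decrements = dec,
                 extras = extras),
            class = "eq5d_value_set")
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set '", x$name, "' (constant ", x$constant, ")\n",
      sep = "")
  print(x$decrements)
  for (e in x$extras)
    cat("  extra: ", e$predicate, " -> -", e$value, "\n", sep = "")
  invisible(x)
}

#' Load a packaged or user-supplied EQ-5D-3L value set
#'
#' The package ships two published tariffs as JSON files:
#' `"NL"` (Dutch tariff, Lamers et al. 2006, Health Econ 15:1121-1132) and
#' `"UK"` (MVH/Dolan 1996 time-trade-off tariff). Any other argument is
#' treated as a path to a JSON file with the same schema:
#' `{name, constant, decrements: {domain: {"2": v, "3": v}}, extras:
#' [{predicate, value}]}`.
#'
#' @param name `"NL"`, `"UK"`, or a file path.
#' @return An `eq5d_value_set`.
#' @export
load_value_set <- function(name) {
  path <- switch(toupper(name),
    NL = system.file("extdata", "valueset_nl_lamers2006.json",
                     package = "qolmap"),
    UK = system.file("extdata", "valueset_uk_mvh1996.json",
                     package = "qolmap"),
    name)
  if (!file.exists(path))
    stop("unknown value set '", name, "' (not a packaged tariff or a file)",
         call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- lapply(js$decrements, function(d) unlist(d))
  value_set(js$name, js$constant, dec,
            extras = lapply(js$extras, function(e)
              list(predicate = e$predicate, value = e$value)))
}

check_eq5d_levels <- function(data) {
  for (d in eq5d_domains()) {
    if (!d %in% names(data))
      stop("missing EQ-5D domain column '", d, "'", call. = FALSE)
    v <- data[[d]]
    bad <- is.na(v) | !v %in% 1:3
    if (any(bad))
      stop("EQ-5D domain '", d, "' has level(s) outside {1,2,3} in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Score EQ-5D-3L responses with a value set
#'
#' @param data Data frame with domain columns `mobility`, `self_care`,
#'   `usual_activities`, `pain_discomfort`, `anxiety_depression`, each in
#'   `{1, 2, 3}`.
#' @param vs An `eq5d_value_set` (see [value_set()], [load_value_set()]).
#' @return Numeric utility vector (attribute `tariff` records the value-set
#'   name). Utilities never exceed the full-health constant; they may be
#'   negative for states worse than dead.
#' @export
eq5d_utility <- function(data, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  data <- as.data.frame(data)
  check_eq5d_levels(data)
  lev <- as.matrix(data[, eq5d_domains(), drop = FALSE])
  u <- rep(vs$constant, nrow(lev))
  for (j in seq_len(5))
    u <- u - vs$decrements[j, ][lev[, j]]
  for (e in vs$extras) {
    trig <- switch(e$predicate,
      any_level_gt1 = rowSums(lev > 1) > 0,
      any_level_3   = rowSums(lev == 3) > 0)
    u <- u - e$value * trig
  }
  u <- unname(u)
  attr(u, "tariff") <- vs$name
  u
}
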