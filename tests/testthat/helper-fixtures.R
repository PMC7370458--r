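# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Toy value set: constant 1, every level-2 decrement 0.1, level-3 0.3,
# no extra terms; all unit tests use this instead of published tariffs.
toy_value_set <- function() {
  doms <- c("mobility", "self_care", "usual_activities", "pain_discomfort",
            "anxiety_depression")
  value_set("toy", 1, stats::setNames(rep(list(c(`2` = 0.1, `3` = 0.3)), 5),
                                      doms))
}

# Published scale-score mapping coefficients (Dutch tariff) used as
# generating truth in recovery tests.
published_linear_coeffs <- function() {
  c(intercept = 0.2993, physical = 0.0021, role = 0.0011,
    emotional = 0.0025, cognitive = 0.0005, social = 0.0006,
    pain = -0.0023, insomnia = -0.0005)
}

# Published beta-regression (disutility scale, logit link) coefficients.
published_beta_coeffs <- function() {
  c(intercept = 2.081, global_health = -0.004, physical = -0.018,
    role = -0.010, emotional = -0.015, cognitive = -0.005,
    pain = 0.014, insomnia = 0.005, financial = 0.007)
}

# Mid-sized cohort shared across model tests (kept small for speed).
small_cohort <- function() cached("small_cohort", {
  generate_cohort(cohort_spec(n_patients = 120, n_rows = 520,
                              n_incomplete = 40), seed = 42)
})

small_scored <- function() cached("small_scored", {
  co <- small_cohort()
  cc <- co[co$complete, ]
  cbind(cc, score_qlqc30(cc)[, qlq_scale_names()])
})

# Full-sized default cohort (study conditions); built once.
default_cohort <- function() cached("default_cohort", {
  generate_cohort(cohort_spec(), seed = 42)
})

# A complete QLQ-C30 record with every item at its given level.
flat_record <- function(level28 = 1, level30 = 7) {
  rec <- as.data.frame(as.list(stats::setNames(rep(level28, 28),
                                               paste0("q", 1:28))))
  rec$q29 <- rec$q30 <- level30
  rec
}
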