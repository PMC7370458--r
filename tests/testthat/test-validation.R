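test_that("fold partition: balanced sizes, remainder to low folds", {
  f <- make_folds(1905, 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(381, 5))
  f2 <- make_folds(10, 3, seed = 1)
  expect_equal(as.vector(table(f2)), c(4, 3, 3))
  expect_identical(make_folds(100, 5, seed = 3), make_folds(100, 5, seed = 3))
  expect_error(make_folds(3, 5), "exceeds")
})

test_that("patient-level folding keeps patients together", {
  pid <- rep(1:30, each = 4)
  f <- make_folds(length(pid), 5, seed = 2, grouping = "patient",
                  patient_id = pid)
  expect_true(all(tapply(f, pid, function(x) length(unique(x))) == 1))
  expect_equal(sort(unique(f)), 1:5)
})

test_that("metrics: perfect, two-point and rank-invariance cases", {
  o <- c(0.2, 0.5, 0.9, 0.4)
  expect_warning(m <- compute_metrics(o, o), "undefined")
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$spearman, 1)
  expect_true(is.na(m$t_p))

  m2 <- suppressWarnings(compute_metrics(c(1, 0), c(0.5, 0.5)))
  expect_equal(m2$rmse, 0.5)
  expect_equal(m2$mae, 0.5)

  m3 <- compute_metrics(o, o^3 + 2)  # strictly monotone transform
  expect_equal(m3$spearman, 1)

  expect_error(compute_metrics(1:3, 1:4), "length")
  w <- capture_warnings(compute_metrics(o, rep(0.5, 4)))
  expect_match(w, "constant", all = FALSE)
})

test_that("RMSE dominates MAE and metrics ignore row order", {
  set.seed(3)
  for (i in 1:25) {
    o <- stats::runif(40)
    p <- o + stats::rnorm(40, 0, 0.2)
    m <- compute_metrics(o, p)
    expect_gte(m$rmse, m$mae)
    perm <- sample(40)
    m_perm <- compute_metrics(o[perm], p[perm])
    expect_equal(m_perm[c("rmse", "mae", "spearman", "mean", "sd")],
                 m[c("rmse", "mae", "spearman", "mean", "sd")],
                 tolerance = 1e-12)
  }
})

test_that("CV with constant predictors reproduces training-fold means", {
  n <- 20
  rec <- flat_record(2, 4)
  cohort <- cbind(data.frame(patient_id = 1:n, visit = 1),
                  rec[rep(1, n), ],
                  data.frame(mobility = 1, self_care = 1,
                             usual_activities = 1, pain_discomfort = 1,
                             anxiety_depression = 1))
  set.seed(9)
  cohort$utility <- stats::runif(n, 0.3, 1)
  cohort$complete <- TRUE
  rownames(cohort) <- NULL
  rep_cv <- suppressWarnings(cross_validate(1, cohort, k = 5, seed = 4))
  fold <- rep_cv$predictions$fold
  for (f in 1:5) {
    expect_equal(unique(rep_cv$predictions$predicted[fold == f]),
                 mean(cohort$utility[fold != f]), tolerance = 1e-8)
  }
})

test_that("pooled held-out predictions cover the whole cohort once", {
  co <- small_cohort()
  rep_cv <- suppressWarnings(cross_validate(1, co, k = 5, seed = 4))
  expect_equal(nrow(rep_cv$predictions), sum(co$complete))
  expect_false(anyNA(rep_cv$predictions$predicted))
  expect_equal(rep_cv$pooled$n, sum(co$complete))
  expect_equal(sum(rep_cv$fold_metrics$n), sum(co$complete))
  rep_cv2 <- suppressWarnings(cross_validate(1, co, k = 5, seed = 4))
  rep_cv$label <- rep_cv2$label  # identical up to environments
  expect_equal(rep_cv$pooled, rep_cv2$pooled, tolerance = 1e-12)
  expect_identical(rep_cv$predictions, rep_cv2$predictions)
})

test_that("pooled CV error approaches the generating noise level", {
  # well-specified linear data: irreducible error = residual noise
  d <- generate_from_linear_model(published_linear_coeffs(), noise_sd = 0.098,
                                  re_sd = 0.02, seed = 17)
  d$complete <- TRUE
  rep_cv <- cross_validate(1, d, k = 5, seed = 17)
  expect_lt(abs(rep_cv$pooled$rmse - 0.098), 0.1 * 0.098)
})

test_that("mapping error shows the documented compression pattern", {
  # overestimation at low utilities, underestimation at high ones
  co <- small_cohort()
  rep_cv <- suppressWarnings(cross_validate(1, co, k = 5, seed = 4))
  pr <- rep_cv$predictions
  err <- pr$predicted - pr$observed
  q <- stats::quantile(pr$observed, c(0.1, 0.9))
  expect_gt(mean(err[pr$observed <= q[1]]), 0)
  expect_lt(mean(err[pr$observed >= q[2]]), 0)
})

test_that("incomplete-questionnaire evaluation respects eligibility", {
  co <- small_cohort()
  cc <- co[co$complete, ]
  full <- cbind(cc, score_qlqc30(cc)[, qlq_scale_names()])
  fits <- list(scale_scores = suppressWarnings(
    prune_nonlogical(backward_select(fit_linear(full, "scale_scores")))),
    response_mapping = fit_response_mapping(full))
  tab <- evaluate_incomplete(co, fits)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$n_eligible <= sum(!co$complete)))
  expect_true(all(tab$rmse >= tab$mae))

  # rows missing a needed symptom item are excluded for the linear model
  inc <- co[!co$complete, ]
  scored <- score_qlqc30(inc)
  need <- intersect(names(fits$scale_scores$model$coefficients),
                    qlq_scale_names())
  eligible <- rowSums(is.na(scored[, need, drop = FALSE])) == 0
  expect_equal(tab$n_eligible[tab$model == "scale_scores"], sum(eligible))

  # with no incomplete rows the path equals complete-data evaluation
  tab_all <- evaluate_incomplete(cc, fits["response_mapping"])
  p <- predict_mapped(fits$response_mapping, full,
                      vs = load_value_set("NL"))
  direct <- compute_metrics(full$utility, p)
  expect_equal(tab_all$rmse, direct$rmse, tolerance = 1e-12)
  expect_equal(tab_all$n_eligible, nrow(cc))
})
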