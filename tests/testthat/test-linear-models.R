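test_that("prediction is the published closed-form algorithm", {
  m <- load_mapping_model(published_algorithm_path())
  full_health <- data.frame(physical = 100, role = 100, emotional = 100,
                            cognitive = 100, social = 100, pain = 0,
                            insomnia = 0)
  expect_equal(predict_linear(m, full_health), 0.2993 + 0.0068 * 100,
               tolerance = 1e-12)
  zeros <- full_health; zeros[] <- 0
  expect_equal(predict_linear(m, zeros), 0.2993, tolerance = 1e-12)
  worst <- full_health; worst[] <- 0; worst$pain <- worst$insomnia <- 100
  expect_equal(predict_linear(m, worst), 0.2993 - 0.28, tolerance = 1e-12)
})

test_that("a missing required predictor is an error naming it", {
  m <- load_mapping_model(published_algorithm_path())
  d <- data.frame(physical = 50, role = 50, emotional = 50, cognitive = 50,
                  social = 50, insomnia = 0)
  expect_error(predict_linear(m, d), "pain")
  d$pain <- NA_real_
  expect_error(predict_linear(m, d), "pain")
})

test_that("noiseless single-cluster data give the exact OLS limit", {
  d <- data.frame(patient_id = 1, visit = 1:30,
                  physical = seq(0, 100, length.out = 30))
  d$utility <- 0.3 + 0.004 * d$physical
  f <- suppressWarnings(fit_linear(d, "scale_scores",
                                   candidates = "physical"))
  expect_equal(unname(f$model$coefficients[["physical"]]), 0.004,
               tolerance = 1e-10)
  expect_equal(f$model$intercept, 0.3, tolerance = 1e-8)
})

test_that("fitting recovers generating signs on synthetic data", {
  d <- generate_from_linear_model(published_linear_coeffs(), n_rows = 800,
                                  n_patients = 200, seed = 21)
  f <- fit_linear(d, "scale_scores",
                  candidates = setdiff(names(published_linear_coeffs()), "intercept"))
  expect_lt(f$model$coefficients[["pain"]], 0)
  expect_gt(f$model$coefficients[["physical"]], 0)
  # cluster-robust table exposes SE, t, p and CI for every term
  expect_true(all(c("estimate", "se", "stat", "p", "conf_low",
                    "conf_high") %in% names(f$coef_table)))
})

test_that("zero-variance candidates are dropped with a warning", {
  d <- generate_from_linear_model(published_linear_coeffs(), n_rows = 300,
                                  n_patients = 60, seed = 3)
  d$diarrhea <- 0
  expect_warning(
    f <- fit_linear(d, "scale_scores",
                    candidates = c("physical", "pain", "diarrhea")),
    "diarrhea")
  expect_false("diarrhea" %in% f$terms)
})

test_that("backward selection is a no-op on well-powered true effects", {
  d <- generate_from_linear_model(published_linear_coeffs(), n_rows = 1500,
                                  n_patients = 300, noise_sd = 0.05,
                                  seed = 9)
  f <- fit_linear(d, "scale_scores",
                  candidates = c("physical", "emotional", "pain"))
  sel <- backward_select(f)
  expect_setequal(sel$terms, c("physical", "emotional", "pain"))
  expect_equal(nrow(sel$history), 0)
})

test_that("selection history length equals the number of removed terms", {
  d <- generate_from_linear_model(c(intercept = 0.5, physical = 0.002),
                                  n_rows = 400, n_patients = 80,
                                  noise_sd = 0.08, seed = 13)
  f <- fit_linear(d, "scale_scores",
                  candidates = c("physical", "diarrhea", "constipation",
                                 "dyspnea"))
  sel <- backward_select(f)
  expect_equal(nrow(sel$history), 4 - length(sel$terms))
  expect_true(all(sel$coef_table$p[sel$coef_table$term != "(Intercept)"]
                  <= 0.05))
})

test_that("a pure-noise candidate is dropped in most replicates", {
  dropped <- vapply(1:50, function(r) {
    d <- generate_from_linear_model(
      c(intercept = 0.4, physical = 0.002, pain = -0.002),
      n_rows = 400, n_patients = 80, noise_sd = 0.08, seed = 500 + r)
    f <- fit_linear(d, "scale_scores",
                    candidates = c("physical", "pain", "diarrhea"))
    !"diarrhea" %in% backward_select(f)$terms
  }, logical(1))
  expect_gte(mean(dropped), 0.9)
})

test_that("wrong-signed coefficients are pruned, conforming ones kept", {
  # a truly positive nausea effect is non-logical on the utility scale
  d <- generate_from_linear_model(
    c(intercept = 0.4, physical = 0.002, pain = -0.002,
      nausea_vomiting = 0.003),
    n_rows = 1000, n_patients = 200, noise_sd = 0.08, seed = 31)
  f <- backward_select(fit_linear(d, "scale_scores",
                                  candidates = c("physical", "pain",
                                                 "nausea_vomiting")))
  expect_true("nausea_vomiting" %in% f$terms)  # significant before pruning
  pruned <- prune_nonlogical(f)
  expect_false("nausea_vomiting" %in% pruned$terms)
  expect_true(any(pruned$history$reason == "sign"))
  # survivors conform in sign and significance
  ct <- pruned$coef_table[pruned$coef_table$term != "(Intercept)", ]
  sgn <- sign_convention(ct$term, "scale_scores", "utility")
  expect_true(all(sign(ct$estimate) == sgn))
  expect_true(all(ct$p <= 0.05))
  # and pruning a conforming model changes nothing
  expect_identical(prune_nonlogical(pruned)$terms, pruned$terms)
})

test_that("sign conventions reverse on the disutility scale", {
  sgn_u <- sign_convention(c("physical", "pain"), "scale_scores")
  expect_equal(unname(sgn_u), c(1, -1))
  expect_equal(unname(sign_convention(c("physical", "pain"), "scale_scores",
                                      "disutility")), c(-1, 1))
  expect_equal(unname(sign_convention(c("q3", "q29"), "continuous_items")),
               c(-1, 1))
  expect_equal(unname(sign_convention(c("q5_2", "q30_7"), "item_dummies")),
               c(-1, 1))
})

test_that("item and dummy families fit and predict on the cohort", {
  d <- small_scored()
  f2 <- suppressWarnings(fit_linear(d, "continuous_items"))
  p2 <- predict_linear(f2, d)
  expect_equal(length(p2), nrow(d))
  f3 <- suppressWarnings(fit_linear(d, "item_dummies"))
  p3 <- predict_linear(f3, d)
  expect_lt(sqrt(mean((p3 - d$utility)^2)), 0.2)
  # dummy terms reference level 1 implicitly
  expect_false(any(grepl("_1$", f3$terms)))
})
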