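test_that("same seed reproduces the cohort exactly", {
  spec <- cohort_spec(n_patients = 40, n_rows = 160, n_incomplete = 10)
  expect_identical(generate_cohort(spec, seed = 7),
                   generate_cohort(spec, seed = 7))
  expect_false(identical(generate_cohort(spec, seed = 7),
                         generate_cohort(spec, seed = 8)))
})

test_that("default cohort matches the reference marginal moments", {
  co <- default_cohort()
  cc <- co[co$complete, ]
  expect_gte(nrow(cc), 1905)
  sc <- score_qlqc30(cc)
  # cluster-aware SE of the mean (patients share a latent trait)
  pat_means <- tapply(sc$physical, cc$patient_id, mean)
  se <- stats::sd(pat_means) / sqrt(length(pat_means))
  expect_lt(abs(mean(sc$physical) - 82.681), 2 * se)
  expect_lt(abs(stats::sd(cc$utility) - 0.171), 0.2 * 0.171)
})

test_that("generated utilities respect the scale ceiling and rare floor", {
  co <- default_cohort()
  expect_true(all(co$utility <= 1))
  # worse-than-dead states are rare but present at the default settings
  big <- generate_cohort(cohort_spec(n_patients = 1000, n_rows = 8000,
                                     n_incomplete = 0), seed = 11)
  frac_neg <- mean(big$utility < 0)
  expect_gt(frac_neg, 0.0002)
  expect_lt(frac_neg, 0.01)
})

test_that("observed utility is consistent with the domain levels", {
  co <- small_cohort()
  nl <- load_value_set("NL")
  expect_equal(co$utility, as.numeric(eq5d_utility(co, nl)))
})

test_that("complete rows score fully and the instruments correlate", {
  co <- small_cohort()
  sc <- score_qlqc30(co[co$complete, ])
  expect_false(anyNA(sc[, qlq_scale_names()]))
  # cross-instrument correlation induced by the shared latent trait
  rho <- stats::cor(co$utility[co$complete], sc$physical,
                    method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("forcing the ceiling gives exact full health", {
  spec <- cohort_spec(n_patients = 30, n_rows = 30, n_incomplete = 0,
                      sd_within = 0, ceiling_mass = 1,
                      extra_negative_rate = 0)
  co <- generate_cohort(spec, seed = 3)
  expect_true(all(co$utility == 1))
})

test_that("item missingness is constrained, calibrated and flag-updating", {
  co <- small_cohort()
  cc <- co[co$complete, ]
  expect_identical(inject_item_missingness(cc, 0, seed = 1), cc)

  gapped <- inject_item_missingness(cc, 0.2, seed = 1)
  expect_false(any(gapped$complete))
  sc <- score_qlqc30(gapped)
  expect_false(anyNA(sc[, qlq_scale_names("functional")]))

  items <- as.matrix(gapped[, paste0("q", 1:30)])
  del_rate <- mean(is.na(items))
  expect_lt(abs(del_rate - 0.2), 0.03)
  expect_error(inject_item_missingness(cc, 0.6), "rate")
})

test_that("linear-model generator: constants, arithmetic and determinism", {
  co1 <- generate_from_linear_model(c(intercept = 0.5), n_rows = 50,
                                    n_patients = 10, noise_sd = 0,
                                    re_sd = 0, seed = 1)
  expect_true(all(co1$utility == 0.5))

  # full-health scores under the published coefficient set
  spec0 <- reference_cohort_moments()
  spec0$sd <- 0
  spec0$mean <- ifelse(spec0$scale %in% qlq_scale_names("functional"), 100,
                       ifelse(spec0$scale == "global_health", 100, 0))
  d <- generate_from_linear_model(published_linear_coeffs(), n_rows = 5,
                                  n_patients = 5, noise_sd = 0, re_sd = 0,
                                  covariate_spec = spec0, seed = 1)
  expect_equal(d$utility, rep(0.2993 + 0.68, 5), tolerance = 1e-12)

  expect_identical(generate_from_linear_model(published_linear_coeffs(), seed = 4),
                   generate_from_linear_model(published_linear_coeffs(), seed = 4))
  expect_error(generate_from_linear_model(c(intercept = 0, bogus = 1)),
               "bogus")
})
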