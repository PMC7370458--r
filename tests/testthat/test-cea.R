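test_that("ICER arithmetic: quotient, homogeneity, dominance boundary", {
  expect_equal(icer(30163, 1), 30163)
  expect_equal(icer(30163, 0.179), 30163 / 0.179)
  expect_equal(icer(30163, 0.179), icer(30163 * 3, 0.179 * 3))
  expect_equal(icer(-5000, 0.1), -50000)
  expect_warning(v <- icer(30163, 0), "dominance")
  expect_true(is.na(v))
})

test_that("method-of-moments beta shapes reproduce their moments", {
  sh <- beta_from_moments(0.5, 0.1)
  expect_equal(unname(sh), c(12, 12))
  set.seed(5)
  for (i in 1:30) {
    m <- stats::runif(1, 0.05, 0.95)
    s <- stats::runif(1, 0.005, 0.9 * sqrt(m * (1 - m)))
    sh <- beta_from_moments(m, s)
    a <- sh[["shape1"]]; b <- sh[["shape2"]]
    expect_equal(a / (a + b), m, tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), s,
                 tolerance = 1e-12)
  }
  expect_error(beta_from_moments(0.5, 0.6), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("sampled moments concentrate on the requested mean", {
  sh <- beta_from_moments(0.83, 0.01)
  set.seed(6)
  x <- stats::rbeta(1e5, sh[["shape1"]], sh[["shape2"]])
  expect_lt(abs(mean(x) - 0.83), 3 * 0.01 / sqrt(1e5))
})

test_that("probabilistic analysis degenerates correctly at zero SE", {
  cfg <- cea_config(utility_obs = c(0.829, 0), utility_trt = c(0.839, 0),
                    n_samples = 500)
  r <- probabilistic_analysis(cfg, seed = 3)
  expect_equal(length(unique(r$cloud$delta_qaly)), 1)
  expect_equal(r$icer, icer(cfg$delta_cost, r$delta_qaly))
  expect_equal(r$ci[1], r$ci[2])
})

test_that("PSA is seeded and its cloud mean matches the point estimate", {
  cfg <- cea_config(utility_obs = c(0.829, 0.008),
                    utility_trt = c(0.839, 0.0055))
  r1 <- probabilistic_analysis(cfg, seed = 11)
  r2 <- probabilistic_analysis(cfg, seed = 11)
  expect_identical(r1$cloud, r2$cloud)
  expect_equal(nrow(r1$cloud), cfg$n_samples)
  mc_se <- stats::sd(r1$cloud$delta_qaly) / sqrt(cfg$n_samples)
  expect_lt(abs(mean(r1$cloud$delta_qaly) - r1$delta_qaly), 3 * mc_se)
  # interval covers the point estimate in this well-behaved config
  expect_gt(r1$icer, r1$ci[1])
  expect_lt(r1$icer, r1$ci[2])
})

test_that("identical sources tie and higher QALY gain lowers the ICER", {
  cfg <- cea_config(utility_obs = c(0.83, 0.008),
                    utility_trt = c(0.84, 0.0055), n_samples = 2000)
  src <- list(a = list(obs = c(0.83, 0.008), trt = c(0.84, 0.0055)),
              b = list(obs = c(0.83, 0.008), trt = c(0.84, 0.0055)),
              c = list(obs = c(0.83, 0.008), trt = c(0.88, 0.0055)))
  cmp <- compare_utility_sources(src, cfg, seed = 2)
  expect_equal(cmp$table$icer_diff[2], 0)
  expect_lt(cmp$table$icer[3], cmp$table$icer[1])
})

test_that("published arm summaries rank the mapped ICER below observed", {
  # higher utilities in both arms lengthen the (longer) treated arm's
  # QALY accrual more, raising the QALY gain and lowering the ICER
  cfg <- cea_config(utility_obs = c(0.829, 0.0080),
                    utility_trt = c(0.839, 0.0055), n_samples = 2000)
  src <- list(observed = list(obs = c(0.829, 0.0080),
                              trt = c(0.839, 0.0055)),
              mapped = list(obs = c(0.876, 0.0052),
                               trt = c(0.875, 0.0040)))
  cmp <- compare_utility_sources(src, cfg, seed = 5)
  expect_lt(cmp$table$icer[2], cmp$table$icer[1])
  expect_lt(cmp$table$icer_diff[2], 0)
})
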