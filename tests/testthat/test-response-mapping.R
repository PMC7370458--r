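make_domain <- function(beta, zeta) list(coefficients = beta, zeta = zeta)

test_that("level probabilities follow the closed-form logistic arithmetic", {
  # latent L = 0 with threshold offset log(3): (0.5, 0.25, 0.25)
  dm <- make_domain(c(physical = 0), zeta = c(0, log(3)))
  p <- domain_level_probs(dm, data.frame(physical = 50))
  expect_equal(as.numeric(p), c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # L -> -Inf: all mass on level 1
  dm2 <- make_domain(c(physical = 1), zeta = c(200, 201))
  p2 <- domain_level_probs(dm2, data.frame(physical = 0))
  expect_equal(as.numeric(p2), c(1, 0, 0), tolerance = 1e-12)
})

test_that("probabilities always normalise", {
  set.seed(4)
  for (i in 1:50) {
    dm <- make_domain(stats::setNames(stats::rnorm(5, 0, 0.1),
                                      qlq_scale_names("functional")),
                      zeta = sort(stats::rnorm(2, 0, 2)))
    sc <- as.data.frame(matrix(stats::runif(5 * 20, 0, 100), ncol = 5,
                               dimnames = list(NULL,
                                               qlq_scale_names("functional"))))
    p <- domain_level_probs(dm, sc)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
    expect_true(all(p >= -1e-12))
  }
})

test_that("fitted thresholds increase and refits are deterministic", {
  d <- small_scored()
  m1 <- fit_response_mapping(d)
  m2 <- fit_response_mapping(d)
  for (dom in names(m1$domains)) {
    z <- m1$domains[[dom]]$zeta
    if (length(z) > 1) expect_true(all(diff(z) > 0), info = dom)
    expect_equal(m1$domains[[dom]]$coefficients,
                 m2$domains[[dom]]$coefficients, tolerance = 1e-8)
  }
})

test_that("a single driving scale dominates the fitted coefficients", {
  set.seed(8)
  n <- 1500
  sc <- as.data.frame(matrix(stats::runif(5 * n, 0, 100), ncol = 5,
                             dimnames = list(NULL,
                                             qlq_scale_names("functional"))))
  eta <- -0.06 * sc$physical
  zeta <- c(-4, -2)
  u <- stats::runif(n)
  p1 <- stats::plogis(zeta[1] - eta)
  p12 <- stats::plogis(zeta[2] - eta)
  lev <- 1L + (u > p1) + (u > p12)
  d <- cbind(sc, data.frame(mobility = lev, self_care = lev,
                            usual_activities = lev, pain_discomfort = lev,
                            anxiety_depression = lev))
  m <- fit_response_mapping(d)
  cf <- m$domains$mobility$coefficients
  expect_equal(unname(cf[["physical"]]), -0.06, tolerance = 0.15)
  expect_true(all(abs(cf[setdiff(names(cf), "physical")]) <
                    abs(cf[["physical"]]) / 5))
})

test_that("degenerate single-level domains are rejected by name", {
  d <- small_scored()
  d$self_care <- 1L
  expect_error(fit_response_mapping(d), "self_care")
})

test_that("expected-mode utility matches decrement expectation arithmetic", {
  dm <- make_domain(c(physical = 0), zeta = c(0, log(3)))
  model <- structure(list(domains = stats::setNames(rep(list(c(dm,
    list(levels = 1:3))), 5),
    c("mobility", "self_care", "usual_activities", "pain_discomfort",
      "anxiety_depression")),
    predictors = "physical", family = "response_mapping"),
    class = c("response_mapping_model", "mapping_model"))
  u <- predict_response_mapping(model, data.frame(physical = 50),
                                toy_value_set(), mode = "expected")
  expect_equal(as.numeric(u), 1 - 5 * (0.25 * 0.1 + 0.25 * 0.3),
               tolerance = 1e-12)
  # most-likely mode picks level 1 here -> full health
  u_ml <- predict_response_mapping(model, data.frame(physical = 50),
                                   toy_value_set())
  expect_equal(as.numeric(u_ml), 1)
})

test_that("degenerate one-hot probabilities make the two modes agree", {
  dm_low <- make_domain(c(physical = 1), zeta = c(500, 501))  # P(level1)=1
  model <- structure(list(domains = stats::setNames(rep(list(c(dm_low,
    list(levels = 1:3))), 5),
    c("mobility", "self_care", "usual_activities", "pain_discomfort",
      "anxiety_depression")),
    predictors = "physical", family = "response_mapping"),
    class = c("response_mapping_model", "mapping_model"))
  sc <- data.frame(physical = 0)
  u_ml <- predict_response_mapping(model, sc, toy_value_set())
  u_ex <- predict_response_mapping(model, sc, toy_value_set(), "expected")
  expect_equal(as.numeric(u_ml), 1)
  expect_equal(as.numeric(u_ex), 1, tolerance = 1e-10)
  expect_identical(attr(u_ml, "mode"), "most_likely")
  expect_identical(attr(u_ex, "mode"), "expected")
})

test_that("expected-mode utility is invariant to permuting level order", {
  # scoring by expectation only depends on (probability, decrement) pairs
  dm <- make_domain(c(physical = 0.01), zeta = c(0.3, 1.2))
  doms <- c("mobility", "self_care", "usual_activities", "pain_discomfort",
            "anxiety_depression")
  model <- structure(list(domains = stats::setNames(rep(list(c(dm,
    list(levels = 1:3))), 5), doms),
    predictors = "physical", family = "response_mapping"),
    class = c("response_mapping_model", "mapping_model"))
  sc <- data.frame(physical = c(10, 60, 95))
  u <- predict_response_mapping(model, sc, toy_value_set(), "expected")
  p <- domain_level_probs(dm, sc)
  dec <- c(0, 0.1, 0.3)
  manual <- 1 - 5 * as.vector(p %*% dec)
  expect_equal(as.numeric(u), manual, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  manual_perm <- 1 - 5 * as.vector(p[, perm] %*% dec[perm])
  expect_equal(manual_perm, manual, tolerance = 1e-12)
})
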