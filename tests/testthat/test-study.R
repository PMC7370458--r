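small_config <- function(families = 1:6, seed = 5) {
  study_config(cohort = cohort_spec(n_patients = 80, n_rows = 320,
                                    n_incomplete = 30),
               families = families, seed = seed)
}

test_that("a restricted configuration yields exactly one CV report", {
  rep1 <- suppressWarnings(run_study(small_config(families = 1),
                                     quiet = TRUE))
  expect_equal(length(rep1$cv), 1)
  expect_equal(names(rep1$cv), "scale_scores")
  expect_equal(nrow(rep1$cv_table), 2)  # observed + one model
})

test_that("the study is deterministic and its artifacts well-formed", {
  dir_a <- file.path(tempdir(), "study_a")
  dir_b <- file.path(tempdir(), "study_b")
  cfg <- small_config(families = c(1, 4, 5))
  rep_a <- suppressWarnings(run_study(cfg, out_dir = dir_a, quiet = TRUE))
  rep_b <- suppressWarnings(run_study(cfg, out_dir = dir_b, quiet = TRUE))
  expect_identical(readLines(file.path(dir_a, "report.json")),
                   readLines(file.path(dir_b, "report.json")))

  # exported tables: parseable numbers at 3 decimals, idempotent re-export
  tab <- utils::read.csv(file.path(dir_a, "table_cv.csv"))
  expect_equal(tab$model[1], "observed")
  expect_equal(nrow(tab), 4)
  num <- unlist(tab[sapply(tab, is.numeric)])
  expect_true(all(is.finite(num) | is.na(num)))
  expect_true(all(abs(num * 1000 - round(num * 1000)) < 1e-9, na.rm = TRUE))
  before <- readLines(file.path(dir_a, "table_cv.csv"))
  export_tables(rep_a, dir_a)
  expect_identical(readLines(file.path(dir_a, "table_cv.csv")), before)

  # fitted coefficient files exist and reload
  for (fam in c("scale_scores", "response_mapping", "beta")) {
    path <- file.path(dir_a, "models", paste0(fam, ".json"))
    expect_true(file.exists(path))
    expect_s3_class(load_mapping_model(path), "mapping_model")
  }
  # provenance is complete
  expect_true(all(c("seed", "n_complete", "families", "package_version")
                  %in% names(rep_a$provenance)))
})

test_that("incomplete-questionnaire table covers the scale-score models", {
  rep1 <- suppressWarnings(run_study(small_config(families = c(1, 4, 5, 6)),
                                     quiet = TRUE))
  expect_setequal(rep1$incomplete_table$model,
                  c("scale_scores", "response_mapping", "beta",
                    "separate_equations"))
  expect_true(all(rep1$incomplete_table$n_eligible <= 30))
})

test_that("stage failures halt with the stage name", {
  cfg <- small_config(families = 6)
  cfg$cohort$ceiling_mass <- 1  # all utilities 1: class 'low' empty
  expect_error(suppressWarnings(run_study(cfg, quiet = TRUE)),
               "stage 'fit'")
})

test_that("the CEA comparison uses the observed source as reference", {
  rep1 <- suppressWarnings(run_study(small_config(families = 1),
                                     quiet = TRUE))
  expect_equal(rep1$cea_table$source[1], "observed")
  expect_equal(rep1$cea_table$icer_diff[1], 0)
  expect_equal(nrow(rep1$cea_table), 2)
  expect_true(all(is.finite(rep1$cea_table$icer)))
})
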