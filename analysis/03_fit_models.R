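#!/usr/bin/env Rscript
# Stage 3 — estimate the six mapping-model families on the complete data.
#
# Families: (1) random-intercept linear model on scale scores, (2) on the
# 30 items as continuous covariates, (3) on item-level dummies, (4)
# response mapping by ordered logit per EQ-5D domain, (5) beta regression
# on transformed disutilities, (6) separate-equations mixture. Families
# 1-3, 5 and the linear parts of 6 undergo backward selection (p = 0.05)
# and removal of non-logical (wrong-signed) coefficients. Writes one
# coefficient JSON per family under results/models/.

library(qolmap)

scored <- read.csv("results/scored.csv")
full <- scored[scored$complete, ]
nl <- load_value_set("NL")
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

for (fam in c("scale_scores", "continuous_items", "item_dummies",
              "response_mapping", "beta", "separate_equations")) {
  cat("\n==", fam, "==\n")
  fit <- suppressWarnings(fit_family(full, fam, vs = nl))
  if (inherits(fit, "qolmap_fit")) {
    print(fit$coef_table, digits = 4)
    if (nrow(fit$history)) {
      cat("removed terms:\n")
      print(fit$history)
    }
  }
  save_mapping_model(fit, file.path("results/models",
                                    paste0(fam, ".json")),
                     name = fam, tariff = "NL")
}
cat("\nwritten: results/models/*.json\n")
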