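#!/usr/bin/env Rscript
# Stage 4 — 5-fold cross-validated performance of all six families.
#
# Each fold's model is re-estimated from scratch on the other four folds
# (including selection and pruning) and evaluated on the held-out fold.
# Writes the pooled comparison table (results/table_cv.csv) and the
# held-out predictions for scatter/error diagnostics
# (results/cv_predictions.csv: observed, predicted, error, model).

library(qolmap)

seed <- 1905L
cohort <- read.csv("results/cohort.csv")
nl <- load_value_set("NL")

tab <- NULL
preds <- NULL
for (fam in c("scale_scores", "continuous_items", "item_dummies",
              "response_mapping", "beta", "separate_equations")) {
  cv <- suppressWarnings(cross_validate(fam, cohort, k = 5, seed = seed,
                                        vs = nl))
  cat("\n", cv$label, "\n", sep = "")
  print(cv$pooled, digits = 3)
  tab <- rbind(tab, cbind(data.frame(model = fam), cv$pooled))
  preds <- rbind(preds, data.frame(model = fam,
                                   observed = cv$predictions$observed,
                                   predicted = cv$predictions$predicted,
                                   error = cv$predictions$predicted -
                                     cv$predictions$observed))
}

obs <- cohort$utility[cohort$complete]
tab <- rbind(data.frame(model = "observed", n = length(obs),
                        mean = mean(obs), sd = sd(obs), min = min(obs),
                        max = max(obs), rmse = NA, mae = NA,
                        spearman = NA, t_p = NA), tab)
num <- sapply(tab, is.numeric)
tab[num] <- lapply(tab[num], round, 3)
write.csv(tab, "results/table_cv.csv", row.names = FALSE)
write.csv(preds, "results/cv_predictions.csv", row.names = FALSE)
cat("\nwritten: results/table_cv.csv, results/cv_predictions.csv\n")
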