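#!/usr/bin/env Rscript
# Stage 5 — evaluate the scale-score families on incomplete questionnaires.
#
# The families whose predictors are scale scores (1, 4, 5, 6) can predict
# for questionnaires with item gaps as long as the half-completion rule
# leaves their scales computable. Models fitted on the complete data
# (stage 3) are evaluated on the eligible incomplete records; no
# imputation. Writes results/table_incomplete.csv.

library(qolmap)

cohort <- read.csv("results/cohort.csv")
nl <- load_value_set("NL")

fits <- list(
  scale_scores = load_mapping_model("results/models/scale_scores.json"),
  response_mapping =
    load_mapping_model("results/models/response_mapping.json"),
  beta = load_mapping_model("results/models/beta.json"),
  separate_equations =
    load_mapping_model("results/models/separate_equations.json")
)

tab <- evaluate_incomplete(cohort, fits, vs = nl)
num <- sapply(tab, is.numeric)
tab[num] <- lapply(tab[num], round, 3)
print(tab)
write.csv(tab, "results/table_incomplete.csv", row.names = FALSE)
cat("written: results/table_incomplete.csv\n")
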