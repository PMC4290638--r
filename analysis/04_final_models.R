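#!/usr/bin/env Rscript
# Stage 4: final full-data prediction models.
#
# Fits the logistic model on the complete planted cohort for (a) the
# most-selected small subset and (b) the best subset of the GA batch,
# reporting coefficients, Wald z-tests and the rendered model equation.
#
# Writes under results/:
#   final_model_planted.json  - the {3,5,18} model
#   final_model_best.json     - the batch's best subset model

library(gacog)
dir.create("results", showWarnings = FALSE)

pl <- read_cohort_csv("scratch/cohort_planted.csv")
batch <- readRDS("scratch/ga_batch.rds")

rep_small <- final_model_report(pl, c(3, 5, 18), label = "tHCcon")
message("planted-subset model: ", rep_small$equation)
message(sprintf("  Wald p: %s",
                paste(sprintf("%s=%.3g", rep_small$coefficients$term[-1],
                              rep_small$coefficients$p[-1]), collapse = ", ")))
logistic_fit_json(rep_small$fit, "results/final_model_planted.json")

best_row <- batch$run_table[which.max(batch$run_table$mc_auc), ]
best <- as.integer(strsplit(best_row$variables, ";")[[1]])
rep_best <- final_model_report(pl, best, label = "tHCcon")
message(sprintf("best GA subset (MC AUC %.3f): %s",
                best_row$mc_auc, rep_best$equation))
logistic_fit_json(rep_best$fit, "results/final_model_best.json")
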