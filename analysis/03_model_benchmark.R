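#!/usr/bin/env Rscript
# Step 3 -- five-fold cross-validated benchmark of the five learners on the
# selected features, with the hospital-like cohort as the external
# validation set. Writes the full performance panel and the logistic odds
# ratios that drive index construction in step 4.

suppressMessages(library(psaiiscreen))
seed <- 20240603

schema <- function(path) setdiff(names(read.csv(path, nrows = 1)),
                                 c("subject_id", "label", "cohort"))
nh <- load_cohort("results/cohort_nhanes_like.csv",
                  schema("results/cohort_nhanes_like.csv"))
ch <- load_cohort("results/cohort_chinese_like.csv",
                  schema("results/cohort_chinese_like.csv"))
features <- readLines("results/selected_features.txt")
cat("benchmarking on features:", paste(features, collapse = ", "), "\n")

folds <- make_folds(nrow(nh), 5, seed = seed)
results <- lapply(c("LR", "KNN", "GBDT", "NN", "RF"), function(l) {
  cat("  fitting", l, "...\n")
  train_eval(l, nh, features, folds, seed = seed + 1)
})
panel <- compare_models(results, external = ch)
write.csv(panel, "results/model_panel.csv", row.names = FALSE)

show <- panel[, c("model", "partition", "auc", "accuracy", "recall",
                  "specificity", "youden", "kappa", "cutoff")]
show[, 3:9] <- round(show[, 3:9], 3)
print(show, row.names = FALSE)

lr <- results[[1]]
ors <- data.frame(feature = names(lr$odds_ratios),
                  beta = unname(lr$coefficients),
                  odds_ratio = unname(lr$odds_ratios))
write.csv(ors, "results/lr_odds_ratios.csv", row.names = FALSE)
cat("\nlogistic odds ratios (per min-max-normalized unit):\n")
print(transform(ors, beta = round(beta, 3),
                odds_ratio = signif(odds_ratio, 3)), row.names = FALSE)
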