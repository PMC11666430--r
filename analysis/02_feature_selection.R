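#!/usr/bin/env Rscript
# Step 2 -- univariate AUC screen, correlation exclusion and LASSO selection
# on the development cohort. Candidates are restricted to variables present
# in both cohorts so the externally validated model never depends on a
# survey-only variable.

suppressMessages(library(psaiiscreen))
seed <- 20240602

nh <- load_cohort("results/cohort_nhanes_like.csv",
                  schema = setdiff(names(read.csv(
                    "results/cohort_nhanes_like.csv", nrows = 1)),
                    c("subject_id", "label", "cohort")))
ch_names <- names(read.csv("results/cohort_chinese_like.csv", nrows = 1))
candidates <- intersect(cohort_variables(nh),
                        setdiff(ch_names, c("subject_id", "label",
                                            "cohort")))

norm <- fit_minmax(nh, candidates)
sel <- screen_features(minmax_normalize(norm, nh),
                       selection_config(seed = seed, rule = "1se"),
                       candidates)
selection_json(sel, "results/selection.json")

cat("variables flagged by the univariate AUC screen (> 0.6):\n  ",
    paste(sel$flagged, collapse = ", "), "\n")
cat("dropped as the lower-AUC member of a correlated pair:",
    if (length(sel$dropped_correlated))
      paste(sel$dropped_correlated, collapse = ", ") else "none", "\n")
cat("LASSO-selected features (1-SE penalty", signif(sel$lambda, 3), "):\n  ",
    paste(sel$selected, collapse = ", "), "\n")
writeLines(sel$selected, "results/selected_features.txt")
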