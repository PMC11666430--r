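#!/usr/bin/env Rscript
# Step 4 -- construct the serum index from the logistic odds-ratio signs,
# score the full index catalogue on both cohorts, evaluate each index
# (cutoff fixed on the development cohort), and run the adjusted logistic
# and restricted-cubic-spline association analyses for PSAII.

suppressMessages(library(psaiiscreen))
seed <- 20240604

schema <- function(path) setdiff(names(read.csv(path, nrows = 1)),
                                 c("subject_id", "label", "cohort"))
nh <- load_cohort("results/cohort_nhanes_like.csv",
                  schema("results/cohort_nhanes_like.csv"))
ch <- load_cohort("results/cohort_chinese_like.csv",
                  schema("results/cohort_chinese_like.csv"))

ors_tab <- read.csv("results/lr_odds_ratios.csv")
ors <- setNames(ors_tab$odds_ratio, ors_tab$feature)
serum <- names(Filter(function(s) s$role == "serum",
                      cohort_summary_specs("nhanes", quiet = TRUE)))
constructed <- construct_index_from_ors(ors,
                                        eligible = intersect(names(ors),
                                                             serum),
                                        scale = 10, name = "constructed")
cat("constructed index: (",
    paste(constructed$numerator, collapse = " x "), ") / (",
    paste(constructed$denominator, collapse = " x "), " x 10 )\n")

catalogue <- index_catalogue()
catalogue$constructed <- constructed
nh_s <- score_indices(nh, catalogue)
ch_s <- score_indices(ch, catalogue)

panels <- lapply(catalogue, function(defn) {
  cutoff <- select_cutoff(nh_s[[defn$name]], nh$label, defn$orientation)
  rbind(cbind(data.frame(index = defn$name, partition = "development"),
              evaluation_report(nh_s[[defn$name]], nh$label, cutoff,
                                defn$orientation, seed = seed)),
        cbind(data.frame(index = defn$name, partition = "external"),
              evaluation_report(ch_s[[defn$name]], ch$label, cutoff,
                                defn$orientation, seed = seed)))
})
panel <- do.call(rbind, panels)
rownames(panel) <- NULL
write.csv(panel, "results/index_panel.csv", row.names = FALSE)
show <- panel[, c("index", "partition", "auc", "auc_lower", "auc_upper",
                  "recall", "specificity", "cutoff")]
show[, 3:8] <- round(show[, 3:8], 3)
print(show, row.names = FALSE)

# association analyses for PSAII on the pooled cohorts
pooled <- rbind(nh_s[c("label", "PSAII", "age", "gender", "bmi",
                       "diabetes", "hypertension")],
                ch_s[c("label", "PSAII", "age", "gender", "bmi",
                       "diabetes", "hypertension")])
adj <- adjusted_logistic_or(pooled, "PSAII",
                            c("age", "gender", "bmi", "diabetes",
                              "hypertension"))
cat(sprintf("\nadjusted PSAII odds ratio per unit: %.3f (95%% CI %.3f-%.3f, p=%.2g)\n",
            adj$or, adj$lower, adj$upper, adj$p))
rcs <- rcs_logistic(pooled, "PSAII",
                    c("age", "gender", "bmi", "diabetes", "hypertension"),
                    knots = 4)
write.csv(rcs$curve, "results/psaii_spline_curve.csv", row.names = FALSE)
cat(sprintf("spline nonlinearity p = %.3g; curve rises monotonically over %.0f%% of the grid\n",
            rcs$p_nonlinear, 100 * mean(diff(rcs$curve$or) > 0)))
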