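#!/usr/bin/env Rscript
# Step 5 -- the combined PSAII + ToPAS triage rule on the external cohort.
# The serum generator cannot produce the arthralgia complaint or the ToPAS
# questionnaire score, so both are simulated as labelled stand-ins (PSA
# subjects complain of joint pain more often and score higher on ToPAS).

suppressMessages(library(psaiiscreen))
seed <- 20240605
set.seed(seed)

schema <- function(path) setdiff(names(read.csv(path, nrows = 1)),
                                 c("subject_id", "label", "cohort"))
ch <- load_cohort("results/cohort_chinese_like.csv",
                  schema("results/cohort_chinese_like.csv"))
ch <- score_indices(ch, index_catalogue()["PSAII"])

grp <- ifelse(ch$label == 1, "psa", "pso")
ch$arthralgia <- rbinom(nrow(ch), 1,
                        c(pso = 0.2, psa = 0.8)[grp]) == 1
ch$topas <- pmax(0, pmin(12, round(rnorm(nrow(ch),
                                         c(pso = 4, psa = 8)[grp], 2))))

tri <- triage_cohort(ch)
write.csv(tri, "results/triage.csv", row.names = FALSE)
tab <- table(risk = tri$risk, psa = ch$label)
print(tab)
sens <- tab["high", "1"] / sum(tab[, "1"])
spec <- tab["low", "0"] / sum(tab[, "0"])
cat(sprintf("triage sensitivity %.2f, specificity %.2f on the external cohort\n",
            sens, spec))
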