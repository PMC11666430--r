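# Independent brute-force oracles and small fixture builders.

# all-pairs concordance AUC, ties one half
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# exhaustive cutoff search: min |sens - spec|, ties by larger Youden then
# smaller threshold; strict > (or <) classification
oracle_cutoff <- function(scores, labels, orientation = "higher") {
  cand <- sort(unique(scores))
  best <- NULL
  for (c0 in cand) {
    pred <- if (orientation == "higher") scores > c0 else scores < c0
    sens <- mean(pred[labels == 1])
    spec <- mean(!pred[labels == 0])
    row <- c(cut = c0, d = abs(sens - spec), j = sens + spec - 1)
    if (is.null(best) ||
        row["d"] < best["d"] - 1e-15 ||
        (abs(row["d"] - best["d"]) < 1e-15 && row["j"] > best["j"] + 1e-15)) {
      best <- row
    }
  }
  unname(best["cut"])
}

# explicit arithmetic for each catalogue index
oracle_index <- function(name, v) {
  switch(name,
    SII = v["platelet_count"] * v["neutrophil_count"] / v["lymphocyte_count"],
    NLR = v["neutrophil_count"] / v["lymphocyte_count"],
    PLR = v["platelet_count"] / v["lymphocyte_count"],
    LMR = v["lymphocyte_count"] / v["monocyte_count"],
    NPR = v["neutrophil_count"] / v["platelet_count"],
    SIM = v["monocyte_count"] * v["neutrophil_count"] / v["lymphocyte_count"],
    PAR = v["platelet_count"] / v["albumin"],
    CALLY = v["albumin"] * v["lymphocyte_count"] / (v["crp"] * 10),
    PSAII = v["lymphocyte_pct"] * v["crp"] /
      (v["neutrophil_count"] * v["eosinophil_count"] * 10)
  )
}

random_component_vector <- function() {
  v <- stats::runif(8, 0.05, 10)
  names(v) <- c("platelet_count", "neutrophil_count", "lymphocyte_count",
                "monocyte_count", "albumin", "crp", "lymphocyte_pct",
                "eosinophil_count")
  v["platelet_count"] <- stats::runif(1, 100, 400)
  v["lymphocyte_pct"] <- stats::runif(1, 10, 50)
  v
}

# small two-class cohort with one informative and several noise variables
toy_cohort <- function(n = 60, seed = 42, informative_shift = 2) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  data.frame(
    subject_id = seq_len(n), label = label, cohort = "toy",
    signal = stats::rnorm(n) + informative_shift * label,
    noise1 = stats::rnorm(n),
    noise2 = stats::rnorm(n),
    noise3 = stats::rnorm(n)
  )
}

# random confusion table with positive total
random_confusion <- function() {
  repeat {
    c0 <- list(tp = sample(0:30, 1), fp = sample(0:30, 1),
               tn = sample(0:30, 1), fn = sample(0:30, 1))
    if (c0$tp + c0$fp + c0$tn + c0$fn > 0) return(c0)
  }
}
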