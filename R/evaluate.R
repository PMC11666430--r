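#' Screening-performance evaluation
#'
#' Metrics used throughout the screening analyses: pairwise-concordance AUC
#' with DeLong or bootstrap confidence intervals, the sensitivity/specificity
#' balancing cutoff, confusion counts under the strict classification rule,
#' the printed-formula metric panel (accuracy, precision, recall,
#' specificity), Youden index, Cohen's kappa, calibration curves,
#' decision-curve net benefit, covariate-adjusted logistic odds ratios and
#' restricted-cubic-spline dose-response curves.
#'
#' @name evaluation
NULL

.check_two_class <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
}

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half; equals the trapezoidal area under the empirical
#' ROC curve. Computed via midranks.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels 0/1 labels
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  .check_two_class(labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# DeLong structural components: V10 over positives, V01 over negatives
.delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' Confidence interval for the AUC
#'
#' DeLong uses the structural-components variance estimator; bootstrap uses
#' the percentile interval over stratified (within-class) resamples.
#' Intervals are clipped to \[0, 1\].
#'
#' @param scores,labels as in [roc_auc()]
#' @param method `"delong"` or `"bootstrap"`
#' @param level confidence level
#' @param seed seed for the bootstrap
#' @param n_boot bootstrap resamples (>= 1000)
#' @return list with `auc`, `lower`, `upper`, `method`
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   level = 0.95, seed = 1, n_boot = 2000) {
  method <- match.arg(method)
  .check_two_class(labels)
  auc <- roc_auc(scores, labels)
  if (method == "delong") {
    cmp <- .delong_components(scores, labels)
    v <- stats::var(cmp$v10) / length(cmp$v10) +
      stats::var(cmp$v01) / length(cmp$v01)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- auc - z * sqrt(max(v, 0))
    hi <- auc + z * sqrt(max(v, 0))
  } else {
    stopifnot(n_boot >= 1000)
    set.seed(as.integer(seed))
    ip <- which(labels == 1); in_ <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ip, length(ip), TRUE), sample(in_, length(in_), TRUE))
      roc_auc(scores[i], labels[i])
    }, 0)
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(auc = auc, lower = max(0, min(lo, auc)),
       upper = min(1, max(hi, auc)), method = method)
}

# sensitivity/specificity at one cutoff under the strict rule
.sens_spec <- function(scores, labels, cutoff, orientation) {
  pred <- classify_index(scores, cutoff, orientation)
  c(sens = mean(pred[labels == 1] == 1),
    spec = mean(pred[labels == 0] == 0))
}

#' Cutoff balancing sensitivity and specificity
#'
#' Scans the distinct observed scores as candidate cutoffs and returns the
#' one minimizing |sensitivity - specificity| under the strict
#' classification rule; ties are broken by larger Youden index, then by the
#' smaller threshold, so the result is deterministic.
#'
#' @param scores,labels as in [roc_auc()]
#' @param orientation `"higher"` or `"lower"` (see [classify_index()])
#' @return the selected cutoff
#' @export
select_cutoff <- function(scores, labels, orientation = "higher") {
  .check_two_class(labels)
  cand <- sort(unique(scores))
  ss <- vapply(cand, function(c0) .sens_spec(scores, labels, c0,
                                             orientation), c(0, 0))
  sens <- ss[1, ]; spec <- ss[2, ]
  if (all(pmin(sens, spec) == 0)) {
    warning("degenerate scores: no cutoff separates the classes")
  }
  d <- abs(sens - spec)
  best <- which(d == min(d))
  yo <- sens[best] + spec[best] - 1
  best <- best[yo == max(yo)]
  cand[min(best)]
}

#' Confusion counts at a cutoff
#'
#' @param scores,labels as in [roc_auc()]
#' @param cutoff finite cutoff
#' @param orientation classification orientation
#' @return list with `tp`, `fp`, `tn`, `fn`
#' @export
confusion <- function(scores, labels, cutoff, orientation = "higher") {
  if (!length(scores)) stop("empty scores")
  stopifnot(is.finite(cutoff))
  pred <- classify_index(scores, cutoff, orientation)
  list(tp = sum(pred == 1 & labels == 1),
       fp = sum(pred == 1 & labels == 0),
       tn = sum(pred == 0 & labels == 0),
       fn = sum(pred == 0 & labels == 1))
}

#' The four printed confusion metrics
#'
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP). A zero denominator yields `NA` with a warning.
#'
#' @param c confusion counts from [confusion()]
#' @return named list of the four metrics
#' @export
basic_metrics <- function(c) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  n <- c$tp + c$tn + c$fp + c$fn
  list(accuracy = safe(c$tp + c$tn, n, "accuracy"),
       precision = safe(c$tp, c$tp + c$fp, "precision"),
       recall = safe(c$tp, c$tp + c$fn, "recall"),
       specificity = safe(c$tn, c$tn + c$fp, "specificity"))
}

#' Youden index
#' @param sensitivity,specificity rates in \[0, 1\]
#' @return sensitivity + specificity - 1
#' @export
youden <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  sensitivity + specificity - 1
}

#' Cohen's kappa from a confusion table
#'
#' Chance-corrected agreement `(p_o - p_e)/(1 - p_e)` with chance agreement
#' from the marginals; degenerate `p_e = 1` returns 0 with a warning.
#'
#' @param c confusion counts from [confusion()]
#' @return kappa in \[-1, 1\]
#' @export
cohen_kappa <- function(c) {
  n <- c$tp + c$tn + c$fp + c$fn
  stopifnot(n > 0)
  po <- (c$tp + c$tn) / n
  pe <- ((c$tp + c$fp) * (c$tp + c$fn) +
           (c$tn + c$fn) * (c$tn + c$fp)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate marginals (p_e = 1); kappa reported as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Wilson score interval for a proportion
#' @param x successes
#' @param n trials
#' @param level confidence level
#' @return c(lower, upper)
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# bootstrap percentile CI for kappa
.kappa_ci <- function(scores, labels, cutoff, orientation, level = 0.95,
                      n_boot = 1000, seed = 1) {
  set.seed(as.integer(seed))
  n <- length(scores)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, TRUE)
    if (length(unique(labels[i])) < 2) return(NA_real_)
    cohen_kappa(confusion(scores[i], labels[i], cutoff, orientation))
  }, 0)
  stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}

#' Full evaluation report for a score vector
#'
#' One row of the performance panel: AUC with 95% CI (DeLong), the four
#' confusion metrics with Wilson CIs, Youden index, kappa with bootstrap CI,
#' and the cutoff used. When `cutoff` is NULL it is selected on the given
#' data via [select_cutoff()].
#'
#' @param scores,labels as in [roc_auc()]
#' @param cutoff decision cutoff; NULL to select here
#' @param orientation classification orientation
#' @param level confidence level
#' @param seed seed for the kappa bootstrap
#' @return a one-row `data.frame` mirroring the published panel columns
#' @export
evaluation_report <- function(scores, labels, cutoff = NULL,
                              orientation = "higher", level = 0.95,
                              seed = 1) {
  if (is.null(cutoff)) cutoff <- select_cutoff(scores, labels, orientation)
  cm <- confusion(scores, labels, cutoff, orientation)
  bm <- suppressWarnings(basic_metrics(cm))
  a <- auc_ci(scores, labels, "delong", level)
  kci <- .kappa_ci(scores, labels, cutoff, orientation, level, seed = seed)
  wc <- function(x, den) wilson_ci(x, den, level)
  acc_ci <- wc(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  pre_ci <- wc(cm$tp, cm$tp + cm$fp)
  rec_ci <- wc(cm$tp, cm$tp + cm$fn)
  spe_ci <- wc(cm$tn, cm$tn + cm$fp)
  data.frame(
    auc = a$auc, auc_lower = a$lower, auc_upper = a$upper,
    accuracy = bm$accuracy, accuracy_lower = acc_ci[1],
    accuracy_upper = acc_ci[2],
    precision = bm$precision, precision_lower = pre_ci[1],
    precision_upper = pre_ci[2],
    recall = bm$recall, recall_lower = rec_ci[1], recall_upper = rec_ci[2],
    specificity = bm$specificity, specificity_lower = spe_ci[1],
    specificity_upper = spe_ci[2],
    youden = youden(if (is.na(bm$recall)) 0 else bm$recall,
                    if (is.na(bm$specificity)) 0 else bm$specificity),
    kappa = cohen_kappa(cm), kappa_lower = kci[1], kappa_upper = kci[2],
    cutoff = cutoff
  )
}

#' Calibration curve over equal-width probability bins
#'
#' @param probabilities predicted probabilities in \[0, 1\]
#' @param labels 0/1 outcomes
#' @param bins number of equal-width bins on \[0, 1\]
#' @return data.frame with `mean_predicted`, `observed_rate`, `count` for
#'   each nonempty bin
#' @export
calibration_curve <- function(probabilities, labels, bins = 10) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  b <- cut(probabilities, breaks = seq(0, 1, length.out = bins + 1),
           include.lowest = TRUE)
  keep <- levels(b)[tabulate(b, nbins = bins) > 0]
  out <- do.call(rbind, lapply(keep, function(lv) {
    i <- b == lv
    data.frame(mean_predicted = mean(probabilities[i]),
               observed_rate = mean(labels[i]), count = sum(i))
  }))
  rownames(out) <- NULL
  out
}

#' Decision-curve net benefit
#'
#' At threshold probability `t` a subject is called positive iff their
#' predicted probability is at least `t`; net benefit is
#' `TP/n - (FP/n) * t/(1-t)`. The treat-all reference is
#' `prevalence - (1 - prevalence) * t/(1-t)` and treat-none is 0.
#'
#' @param probabilities predicted probabilities
#' @param labels 0/1 outcomes
#' @param thresholds threshold probabilities, all in (0, 1)
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(labels)
  prev <- mean(labels)
  out <- lapply(thresholds, function(t) {
    pos <- probabilities >= t
    tp <- sum(pos & labels == 1)
    fp <- sum(pos & labels == 0)
    w <- t / (1 - t)
    data.frame(threshold = t, net_benefit = tp / n - fp / n * w,
               treat_all = prev - (1 - prev) * w, treat_none = 0)
  })
  do.call(rbind, out)
}

#' Covariate-adjusted logistic odds ratio for an exposure
#'
#' Maximum-likelihood logistic fit of the label on the exposure plus
#' covariates; reports the exposure's per-unit odds ratio with a Wald
#' confidence interval. Constant covariates are dropped with a warning;
#' separation triggers a warning and a ridge-penalized refit (point estimate
#' only).
#'
#' @param table a cohort data.frame with a `label` column
#' @param exposure exposure column name
#' @param covariates covariate column names
#' @param level confidence level
#' @return list with `or`, `lower`, `upper`, `p`, `coef`
#' @export
adjusted_logistic_or <- function(table, exposure, covariates = character(),
                                 level = 0.95) {
  keep <- vapply(covariates, function(v) {
    ok <- length(unique(table[[v]])) > 1
    if (!ok) warning("dropping constant covariate '", v, "'")
    ok
  }, TRUE)
  covariates <- covariates[keep]
  fml <- stats::reformulate(c(exposure, covariates), response = "label")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = table),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || any(abs(stats::coef(fit)) > 20)) {
    warning("separation detected; ridge-penalized refit (no Wald interval)")
    x <- as.matrix(table[c(exposure, covariates)])
    rf <- glmnet::glmnet(x, table$label, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    b <- as.numeric(stats::coef(rf))[match(exposure,
                                           rownames(stats::coef(rf)))]
    return(list(or = exp(b), lower = NA_real_, upper = NA_real_,
                p = NA_real_, coef = b, separation = TRUE))
  }
  sm <- summary(fit)$coefficients
  b <- sm[exposure, "Estimate"]; se <- sm[exposure, "Std. Error"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(b), lower = exp(b - z * se), upper = exp(b + z * se),
       p = sm[exposure, "Pr(>|z|)"], coef = b, separation = FALSE)
}

# Harrell's default knot quantiles
.rcs_knot_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         stop("knots must be 3, 4 or 5"))
}

#' Restricted-cubic-spline logistic dose-response
#'
#' Fits the label on a restricted cubic spline basis of the exposure (linear
#' beyond the boundary knots, continuous second derivative; knots at the
#' standard quantiles) plus covariates, and returns the adjusted
#' dose-response curve normalized to OR = 1 at the exposure median, with a
#' likelihood-ratio test of nonlinearity against the linear-exposure fit.
#'
#' @param table a cohort data.frame with a `label` column
#' @param exposure exposure column name
#' @param covariates covariate column names
#' @param knots number of knots (3, 4 or 5)
#' @param grid_length points of the output exposure grid
#' @param level confidence level of the pointwise interval
#' @return list with `curve` (data.frame: exposure, or, lower, upper),
#'   `p_nonlinear`, `knots`, `reference`
#' @export
rcs_logistic <- function(table, exposure, covariates = character(),
                         knots = 4, grid_length = 100, level = 0.95) {
  x <- table[[exposure]]
  qs <- .rcs_knot_quantiles(knots)
  kn <- unique(stats::quantile(x, qs, names = FALSE))
  if (length(unique(x)) < knots || length(kn) < knots) {
    stop("exposure has fewer distinct values than knots")
  }
  boundary <- kn[c(1, length(kn))]
  inner <- kn[-c(1, length(kn))]
  basis <- function(v) splines::ns(v, knots = inner,
                                   Boundary.knots = boundary)
  B <- basis(x)
  dat <- cbind(data.frame(label = table$label), as.data.frame(unclass(B)))
  names(dat)[-1] <- paste0(".s", seq_len(ncol(B)))
  sp_terms <- names(dat)[-1]
  for (v in covariates) dat[[v]] <- table[[v]]
  fit <- stats::glm(stats::reformulate(c(sp_terms, covariates), "label"),
                    family = stats::binomial(), data = dat)
  lin <- stats::glm(stats::reformulate(c(exposure, covariates), "label"),
                    family = stats::binomial(),
                    data = cbind(dat["label"], table[c(exposure, covariates)]))
  lrt <- stats::anova(lin, fit, test = "Chisq")
  p_nl <- lrt$`Pr(>Chi)`[2]
  ref <- stats::median(x)
  grid <- sort(unique(c(ref, seq(stats::quantile(x, 0.01),
                                 stats::quantile(x, 0.99),
                                 length.out = grid_length))))
  Bg <- stats::predict(B, grid)
  Br <- stats::predict(B, ref)
  D <- sweep(Bg, 2, as.numeric(Br))
  beta <- stats::coef(fit)[sp_terms]
  V <- stats::vcov(fit)[sp_terms, sp_terms, drop = FALSE]
  eta <- as.numeric(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(curve = data.frame(exposure = grid, or = exp(eta),
                          lower = exp(eta - z * se),
                          upper = exp(eta + z * se)),
       p_nonlinear = p_nl, knots = kn, reference = ref)
}
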