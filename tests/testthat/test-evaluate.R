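test_that("ROC AUC matches canonical cases and the all-pairs oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(rnorm(n), 1)
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- rbinom(300, 1, 0.3)
  labels[1:2] <- 0:1
  scores <- rnorm(300) + labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  ci <- auc_ci(scores, labels, "delong")
  ref_ci <- as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"),
                                    method = "delong"))
  expect_equal(c(ci$lower, ci$upper), ref_ci[c(1, 3)], tolerance = 1e-6)
})

test_that("AUC confidence intervals behave at the edges and agree", {
  sep <- auc_ci(c(1, 2, 9, 10), c(0, 0, 1, 1), "bootstrap", seed = 3,
                n_boot = 1000)
  expect_equal(sep$upper, 1)
  set.seed(13)
  labels <- rbinom(800, 1, 0.4); labels[1:2] <- 0:1
  scores <- rnorm(800) + 0.8 * labels
  d <- auc_ci(scores, labels, "delong")
  b <- auc_ci(scores, labels, "bootstrap", seed = 4, n_boot = 1000)
  expect_lt(max(d$lower, b$lower), min(d$upper, b$upper))  # overlap
  expect_true(d$lower <= d$auc && d$auc <= d$upper)
})

test_that("the balanced cutoff matches exhaustive enumeration", {
  expect_equal(select_cutoff(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 0.2)
  # enumeration oracle on the asymmetric case (cutoff 3: sens = spec = 2/3)
  sc <- c(3, 5, 9, 1, 2, 6); lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(select_cutoff(sc, lb), oracle_cutoff(sc, lb))
  expect_equal(select_cutoff(sc, lb), 3)

  expect_warning(deg <- select_cutoff(rep(2, 4), c(0, 1, 0, 1)),
                 "degenerate")
  expect_equal(deg, 2)

  set.seed(14)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)
    orient <- sample(c("higher", "lower"), 1)
    expect_equal(suppressWarnings(select_cutoff(scores, labels, orient)),
                 oracle_cutoff(scores, labels, orient))
  }
})

test_that("confusion counts and the printed metric formulas are exact", {
  cm <- confusion(c(20, 15, 5, 19), c(1, 1, 0, 0), 18, "higher")
  expect_equal(cm, list(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_error(confusion(numeric(0), numeric(0), 1), "empty")

  bm <- basic_metrics(list(tp = 3, tn = 5, fp = 1, fn = 1))
  expect_equal(unlist(bm), c(accuracy = 0.8, precision = 0.75,
                             recall = 0.75, specificity = 5 / 6))
  expect_equal(unlist(basic_metrics(list(tp = 4, tn = 6, fp = 0, fn = 0))),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1))
  expect_warning(bm0 <- basic_metrics(list(tp = 0, fp = 0, tn = 3, fn = 2)),
                 "precision undefined")
  expect_true(is.na(bm0$precision))
})

test_that("Youden and kappa follow their definitions", {
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_equal(youden(0.78, 0.81), 0.59)
  expect_equal(cohen_kappa(list(tp = 10, tn = 10, fp = 0, fn = 0)), 1)
  expect_equal(cohen_kappa(list(tp = 25, fn = 25, fp = 25, tn = 25)), 0)
  expect_equal(cohen_kappa(list(tp = 30, fn = 10, fp = 20, tn = 40)), 0.4)
  expect_warning(k <- cohen_kappa(list(tp = 5, fn = 0, fp = 0, tn = 0)),
                 "degenerate")
  expect_equal(k, 0)
})

test_that("metric panel agrees with spreadsheet recomputation on random tables", {
  set.seed(15)
  for (i in 1:100) {
    cm <- random_confusion()
    n <- cm$tp + cm$fp + cm$tn + cm$fn
    bm <- suppressWarnings(basic_metrics(cm))
    acc <- (cm$tp + cm$tn) / n
    expect_equal(bm$accuracy, acc, tolerance = 1e-12)
    if (cm$tp + cm$fp > 0) {
      expect_equal(bm$precision, cm$tp / (cm$tp + cm$fp), tolerance = 1e-12)
    }
    if (cm$tp + cm$fn > 0 && cm$tn + cm$fp > 0) {
      sens <- cm$tp / (cm$tp + cm$fn); spec <- cm$tn / (cm$tn + cm$fp)
      expect_equal(youden(sens, spec), sens + spec - 1, tolerance = 1e-12)
      po <- acc
      pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
               (cm$tn + cm$fn) * (cm$tn + cm$fp)) / n^2
      if (abs(1 - pe) > 1e-9) {
        expect_equal(suppressWarnings(cohen_kappa(cm)), (po - pe) / (1 - pe),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("calibration bins track the true event rate", {
  set.seed(16)
  p <- runif(1e5)
  y <- rbinom(1e5, 1, p)
  cal <- calibration_curve(p, y, bins = 10)
  expect_lt(max(abs(cal$observed_rate - cal$mean_predicted)), 0.02)
  expect_equal(sum(cal$count), 1e5)

  one <- calibration_curve(rep(0, 5), rep(0, 5))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$mean_predicted, one$observed_rate), c(0, 0))
})

test_that("net benefit follows the decision-curve formula", {
  # 30 true positives and 20 false positives out of 100 at t = 0.25
  p <- c(rep(0.9, 30), rep(0.9, 20), rep(0.1, 50))
  y <- c(rep(1, 30), rep(0, 20), rep(0, 40), rep(1, 10))
  dc <- decision_curve(p, y, thresholds = 0.25)
  expect_equal(dc$net_benefit, 0.3 - 0.2 * (0.25 / 0.75), tolerance = 1e-12)
  expect_equal(dc$treat_none, 0)

  # tiny threshold, everyone called positive: net benefit -> prevalence
  dc0 <- decision_curve(rep(1, 100), rep(c(1, 0), c(40, 60)),
                        thresholds = 0.001)
  expect_equal(dc0$net_benefit, 0.4 - 0.6 * 0.001 / 0.999, tolerance = 1e-12)

  # no positive calls: zero net benefit everywhere
  dcn <- decision_curve(rep(0, 50), rbinom(50, 1, 0.3),
                        thresholds = c(0.2, 0.5, 0.8))
  expect_equal(dcn$net_benefit, c(0, 0, 0))

  # treat-all crosses zero exactly at t = prevalence
  prev <- 0.25
  dca <- decision_curve(rep(1, 8), rep(c(1, 0), c(2, 6)),
                        thresholds = prev)
  expect_equal(dca$treat_all, 0, tolerance = 1e-12)

  expect_error(decision_curve(runif(5), rbinom(5, 1, .5), thresholds = 1.2),
               "inside")
})

test_that("adjusted logistic fits recover a planted exposure effect", {
  set.seed(17)
  n <- 10000
  x <- rnorm(n, 10, 4)
  z <- rnorm(n)
  eta <- -2 + 0.1 * x + 0.3 * z
  tab <- data.frame(label = rbinom(n, 1, plogis(eta)), psaii = x, z = z)
  fit <- adjusted_logistic_or(tab, "psaii", "z")
  expect_equal(fit$coef, 0.1, tolerance = 0.2)
  expect_lt(abs(fit$coef - 0.1), 0.02)
  expect_true(fit$lower <= fit$or && fit$or <= fit$upper)

  tab$const <- 1
  expect_warning(adjusted_logistic_or(tab, "psaii", c("z", "const")),
                 "constant")

  # null exposure: interval straddles 1
  tab0 <- data.frame(label = rbinom(5000, 1, 0.3), psaii = rnorm(5000))
  f0 <- adjusted_logistic_or(tab0, "psaii")
  expect_true(f0$lower < 1 && 1 < f0$upper)
})

test_that("spline dose-response is normalized at the reference and tracks shape", {
  set.seed(18)
  n <- 3000
  x <- rexp(n, 0.1)
  tab <- data.frame(label = rbinom(n, 1, plogis(-3 + 0.08 * x)), psaii = x)
  fit <- rcs_logistic(tab, "psaii", knots = 4)
  # normalization: OR at the reference exposure is exactly 1
  i_ref <- which(fit$curve$exposure == fit$reference)
  expect_equal(fit$curve$or[i_ref], 1, tolerance = 1e-12)
  # monotone-risk generator: curve increases over the central 90%
  qs <- quantile(x, c(0.05, 0.95))
  central <- fit$curve$exposure >= qs[1] & fit$curve$exposure <= qs[2]
  d <- diff(fit$curve$or[central])
  expect_gt(mean(d > 0), 0.9)

  expect_error(rcs_logistic(data.frame(label = rbinom(20, 1, .5),
                                       psaii = rep(1:2, 10)), "psaii"),
               "distinct")
})

test_that("the spline nonlinearity test is calibrated under a linear truth", {
  set.seed(19)
  ps <- vapply(1:10, function(i) {
    n <- 1500
    x <- rnorm(n, 20, 5)
    tab <- data.frame(label = rbinom(n, 1, plogis(-2 + 0.05 * x)),
                      psaii = x)
    rcs_logistic(tab, "psaii", knots = 4)$p_nonlinear
  }, 0)
  expect_lte(sum(ps < 0.05), 3)   # no systematic rejection at the null
})
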