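#' Cross-validated benchmark of five screening learners
#'
#' Five-fold cross-validated comparison of logistic regression (LR), random
#' forest (RF), k-nearest neighbours (KNN), gradient-boosted trees (GBDT)
#' and a single-hidden-layer neural network (NN) on the selected features.
#' Each outer fold is held out once; hyperparameters are chosen by an inner
#' 3-fold cross-validation on the training folds; normalization is refit on
#' the training folds only. The logistic model additionally reports
#' coefficients and odds ratios from a fit on the full table, which feed the
#' index-construction rule.
#'
#' @name model_bench
NULL

.learners <- c("LR", "KNN", "GBDT", "NN", "RF")

#' Balanced random fold assignment
#'
#' Fold sizes differ by at most one; deterministic given the seed.
#'
#' @param n number of subjects
#' @param k number of folds (2 <= k <= n)
#' @param seed integer seed
#' @return list with `fold` (integer vector in 1..k), `k`, `seed`
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  if (n < k || k < 2) stop("need n >= k >= 2")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  list(fold = fold, k = k, seed = as.integer(seed))
}

#' Default hyperparameter grids
#'
#' LR: no penalty or a light L2 ridge. KNN: neighbourhood size. RF: 500
#' trees, bounded or unbounded depth. GBDT: trees x learning rate x depth.
#' NN: one hidden layer of 4, 8 or 16 units.
#'
#' @return named list of per-learner grids (lists of named settings)
#' @export
default_grids <- function() {
  list(
    LR = list(list(penalty = "none"), list(penalty = "l2", lambda = 0.01)),
    KNN = lapply(c(3, 5, 7, 11, 15), function(k) list(k = k)),
    RF = lapply(list(3, 5, NA), function(d)
      list(ntree = 500, depth = d)),
    GBDT = do.call(c, lapply(c(100, 300), function(nt)
      do.call(c, lapply(c(0.05, 0.1), function(eta)
        lapply(c(2, 3), function(d)
          list(nrounds = nt, eta = eta, max_depth = d)))))),
    NN = lapply(c(4, 8, 16), function(s) list(size = s))
  )
}

# fit one learner with one hyperparameter setting; returns a closure that
# predicts class-1 probabilities on a numeric matrix
.fit_learner <- function(learner, x, y, hp) {
  switch(learner,
    LR = {
      if (identical(hp$penalty, "l2")) {
        fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                              lambda = hp$lambda)
        function(newx) as.numeric(stats::predict(fit, newx,
                                                 type = "response"))
      } else {
        df <- as.data.frame(x); df$.y <- y
        fit <- suppressWarnings(
          stats::glm(.y ~ ., family = stats::binomial(), data = df))
        function(newx) as.numeric(stats::predict(fit, as.data.frame(newx),
                                                 type = "response"))
      }
    },
    KNN = {
      fit <- caret::knn3(x, factor(y, levels = c(0, 1)), k = hp$k)
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    RF = {
      fit <- randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = hp$ntree,
        maxnodes = if (is.na(hp$depth)) NULL else 2^hp$depth)
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    GBDT = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = hp$nrounds, verbose = 0)
      function(newx) stats::predict(fit,
                                    xgboost::xgb.DMatrix(newx, nthread = 1))
    },
    NN = {
      fit <- nnet::nnet(x, y, size = hp$size, decay = 0.01, maxit = 200,
                        entropy = TRUE, trace = FALSE)
      function(newx) as.numeric(stats::predict(fit, newx))
    },
    stop("unknown learner '", learner, "'")
  )
}

# inner CV over the grid; returns the best setting by mean held-out AUC
.tune <- function(learner, x, y, grid, inner_k = 3) {
  if (length(grid) == 1) return(grid[[1]])
  fold <- sample(rep(seq_len(inner_k), length.out = nrow(x)))
  score <- vapply(grid, function(hp) {
    mean(vapply(seq_len(inner_k), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        return(NA_real_)
      }
      pred <- .fit_learner(learner, x[tr, , drop = FALSE], y[tr], hp)
      roc_auc(pred(x[!tr, , drop = FALSE]), y[!tr])
    }, 0), na.rm = TRUE)
  }, 0)
  grid[[which.max(score)]]
}

#' Train and evaluate one learner across the outer folds
#'
#' For every outer fold: min-max normalization and the model are fitted on
#' the other folds (hyperparameters by inner 3-fold CV) and the held-out
#' fold is predicted. Resubstitution predictions on the training folds are
#' kept as the training partition. For LR a fit on the whole table provides
#' coefficients and odds ratios `exp(beta)`; every learner also retains a
#' full-table fit for scoring external cohorts. The training cutoff is
#' selected on the pooled training-partition predictions and reused
#' downstream.
#'
#' @param learner one of `"LR"`, `"KNN"`, `"GBDT"`, `"NN"`, `"RF"`
#' @param table a cohort data.frame with a `label` column
#' @param features feature column names
#' @param folds a fold plan from [make_folds()]
#' @param grid hyperparameter grid; default from [default_grids()]
#' @param seed integer seed
#' @return a `model_result` list
#' @export
train_eval <- function(learner, table, features, folds,
                       grid = default_grids()[[learner]], seed = 1) {
  learner <- match.arg(learner, .learners)
  stopifnot(all(features %in% names(table)))
  y <- table$label
  k <- folds$k
  set.seed(as.integer(seed))
  oof <- rep(NA_real_, nrow(table))
  train_pred <- vector("list", k)
  train_idx <- vector("list", k)
  hps <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds$fold != f
    if (length(unique(y[tr])) < 2) {
      stop("degenerate single-class training fold; try a different seed")
    }
    norm <- fit_minmax(table[tr, , drop = FALSE], features)
    xt <- as.matrix(minmax_normalize(norm, table)[features])
    hp <- .tune(learner, xt[tr, , drop = FALSE], y[tr], grid)
    pred <- .fit_learner(learner, xt[tr, , drop = FALSE], y[tr], hp)
    oof[!tr] <- pred(xt[!tr, , drop = FALSE])
    train_pred[[f]] <- pred(xt[tr, , drop = FALSE])
    train_idx[[f]] <- which(tr)
    hps[[f]] <- hp
  }
  # full-table fit (normalization refit on all rows) for external scoring
  norm_all <- fit_minmax(table, features)
  x_all <- as.matrix(minmax_normalize(norm_all, table)[features])
  hp_all <- .tune(learner, x_all, y, grid)
  full_pred <- .fit_learner(learner, x_all, y, hp_all)
  coefs <- ors <- NULL
  if (learner == "LR") {
    df <- as.data.frame(x_all); df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., stats::binomial(), df))
    coefs <- stats::coef(fit)[-1]
    names(coefs) <- features
    ors <- exp(coefs)
  }
  cutoff <- select_cutoff(unlist(train_pred),
                          y[unlist(train_idx)], "higher")
  structure(list(learner = learner, features = features, folds = folds,
                 hyperparameters = hps, oof = oof,
                 train_pred = train_pred, train_idx = train_idx,
                 labels = y, coefficients = coefs, odds_ratios = ors,
                 cutoff = cutoff, norm = norm_all,
                 predict_external = function(newtable) {
                   absent <- setdiff(features, names(newtable))
                   if (length(absent)) {
                     stop("external cohort missing feature(s): ",
                          paste(absent, collapse = ", "))
                   }
                   xn <- as.matrix(
                     minmax_normalize(norm_all, newtable)[features])
                   full_pred(xn)
                 }),
            class = "model_result")
}

# mean-over-folds metric aggregation for one partition of a model_result
.fold_metrics <- function(preds, labels_list, cutoff) {
  rows <- Map(function(p, l) {
    cm <- confusion(p, l, cutoff, "higher")
    bm <- suppressWarnings(basic_metrics(cm))
    c(auc = if (length(unique(l)) > 1) roc_auc(p, l) else NA_real_,
      accuracy = bm$accuracy, precision = bm$precision,
      recall = bm$recall, specificity = bm$specificity,
      youden = youden(if (is.na(bm$recall)) 0 else bm$recall,
                      if (is.na(bm$specificity)) 0 else bm$specificity),
      kappa = cohen_kappa(cm))
  }, preds, labels_list)
  colMeans(do.call(rbind, rows), na.rm = TRUE)
}

#' Performance panel across learners and partitions
#'
#' One row per learner per partition (training = resubstitution on the
#' training folds, held-out = the cross-validated test folds, external =
#' an optional independent cohort), with columns mirroring the published
#' panel: AUC, accuracy, precision, recall, specificity (each with 95% CI
#' computed on the pooled predictions), Youden index, kappa and the
#' training cutoff. Point estimates are the arithmetic means of per-fold
#' metrics at the training cutoff.
#'
#' @param results list of `model_result` objects sharing one fold plan
#' @param external optional external cohort data.frame
#' @param level confidence level
#' @return a data.frame panel
#' @export
compare_models <- function(results, external = NULL, level = 0.95) {
  shared <- vapply(results, function(r)
    identical(r$folds$fold, results[[1]]$folds$fold), TRUE)
  if (!all(shared)) stop("all results must share the fold plan")
  panel <- list()
  for (r in results) {
    k <- r$folds$k
    y <- r$labels
    # training partition: per-fold resubstitution
    tr_rep <- evaluation_report(unlist(r$train_pred), y[unlist(r$train_idx)],
                                cutoff = r$cutoff)
    tr_mean <- .fold_metrics(r$train_pred,
                             lapply(r$train_idx, function(i) y[i]), r$cutoff)
    # held-out partition: per-fold out-of-fold predictions
    ho_pred <- lapply(seq_len(k), function(f) r$oof[r$folds$fold == f])
    ho_lab <- lapply(seq_len(k), function(f) y[r$folds$fold == f])
    ho_rep <- evaluation_report(r$oof, y, cutoff = r$cutoff)
    ho_mean <- .fold_metrics(ho_pred, ho_lab, r$cutoff)
    mk <- function(partition, rep, m) {
      rep$auc <- m[["auc"]]; rep$accuracy <- m[["accuracy"]]
      rep$precision <- m[["precision"]]; rep$recall <- m[["recall"]]
      rep$specificity <- m[["specificity"]]
      rep$youden <- m[["youden"]]; rep$kappa <- m[["kappa"]]
      cbind(data.frame(model = r$learner, partition = partition), rep)
    }
    panel[[length(panel) + 1]] <- mk("training", tr_rep, tr_mean)
    panel[[length(panel) + 1]] <- mk("held-out", ho_rep, ho_mean)
    if (!is.null(external)) {
      ep <- r$predict_external(external)
      ex_rep <- evaluation_report(ep, external$label, cutoff = r$cutoff)
      panel[[length(panel) + 1]] <- cbind(
        data.frame(model = r$learner, partition = "external"), ex_rep)
    }
  }
  out <- do.call(rbind, panel)
  rownames(out) <- NULL
  out
}
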