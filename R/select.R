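#' Feature screening and LASSO selection
#'
#' The published selection pipeline: plot a univariate ROC for every
#' candidate (variables with AUC above 0.6 are flagged as promising),
#' exclude one member of every highly correlated pair, then run an
#' L1-penalized logistic regression with the penalty chosen by ten-fold
#' cross-validation and keep the variables with nonzero coefficients. The
#' AUC screen is advisory only: it flags but never removes (the published
#' final feature set includes a variable whose univariate group difference
#' is not significant).
#'
#' @name feature_selection
NULL

#' Selection configuration
#'
#' @param auc_threshold univariate-AUC flag threshold
#' @param cor_threshold absolute-correlation exclusion threshold
#' @param folds cross-validation folds for the penalty choice
#' @param rule penalty rule: `"1se"` (largest penalty within one standard
#'   error of the CV minimum) or `"min"`
#' @param seed integer seed
#' @param nlambda penalty-path resolution
#' @return a `selection_config` list
#' @export
selection_config <- function(auc_threshold = 0.6, cor_threshold = 0.8,
                             folds = 10, rule = c("1se", "min"), seed = 1,
                             nlambda = 100) {
  rule <- match.arg(rule)
  stopifnot(auc_threshold > 0, auc_threshold < 1,
            cor_threshold > 0, cor_threshold < 1, folds >= 2)
  list(auc_threshold = auc_threshold, cor_threshold = cor_threshold,
       folds = folds, rule = rule, seed = as.integer(seed),
       nlambda = nlambda)
}

#' Univariate AUC of a raw variable as a score for the label
#'
#' Pairwise concordance with ties counted one half. With
#' `direction_free = TRUE` the direction-agnostic `max(AUC, 1 - AUC)` is
#' returned, as used by the screen.
#'
#' @param table a cohort data.frame with a `label` column
#' @param variable variable name
#' @param direction_free report `max(AUC, 1 - AUC)`?
#' @return AUC in \[0, 1\]
#' @export
univariate_auc <- function(table, variable, direction_free = FALSE) {
  a <- roc_auc(table[[variable]], table$label)
  if (direction_free) max(a, 1 - a) else a
}

#' Pairwise correlation matrix of cohort variables
#'
#' Pearson correlations on the encoded numeric variables; a constant
#' variable gets zero correlations with a warning (its correlation is
#' undefined).
#'
#' @param table a cohort data.frame
#' @param variables variables to correlate (>= 2)
#' @return symmetric correlation matrix with unit diagonal
#' @export
correlation_matrix <- function(table, variables = cohort_variables(table)) {
  stopifnot(length(variables) >= 2, nrow(table) >= 3)
  m <- as.matrix(table[variables])
  const <- apply(m, 2, function(col) stats::sd(col) == 0)
  r <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warning("constant variable(s) ", paste(variables[const], collapse = ", "),
            ": correlations reported as 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' L1-penalized logistic selection with cross-validated penalty
#'
#' Fits a LASSO logistic regression over a descending penalty path,
#' chooses the penalty by k-fold cross-validation under the configured rule
#' and returns the variables with nonzero coefficients there. An empty
#' selection is a warning, not an error.
#'
#' @param table a (normalized) cohort data.frame with a `label` column
#' @param candidates candidate variable names
#' @param config a [selection_config()]
#' @return list with `selected`, `lambda`, `coefficients`, `fit` (the
#'   `cv.glmnet` object), and the path's per-penalty nonzero sets
#' @export
lasso_select <- function(table, candidates, config = selection_config()) {
  stopifnot(length(candidates) >= 1)
  x <- as.matrix(table[candidates])
  y <- table$label
  set.seed(config$seed)
  foldid <- sample(rep(seq_len(config$folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = config$nlambda)
  lambda <- if (config$rule == "1se") cv$lambda.1se else cv$lambda.min
  b <- as.matrix(stats::coef(cv, s = lambda))[-1, 1]
  selected <- names(b)[b != 0]
  if (!length(selected)) {
    warning("no variable survives at the chosen penalty")
  }
  path_sets <- apply(as.matrix(cv$glmnet.fit$beta) != 0, 2, function(nz)
    rownames(cv$glmnet.fit$beta)[nz], simplify = FALSE)
  list(selected = selected, lambda = lambda, coefficients = b, fit = cv,
       path_sets = path_sets, path_lambda = cv$glmnet.fit$lambda)
}

#' Full screening pipeline: AUC flag, correlation exclusion, LASSO
#'
#' Computes direction-free univariate AUCs for every candidate, flags those
#' above the threshold, drops the lower-AUC member of every correlated pair
#' above the correlation threshold, then runs [lasso_select()] on the
#' survivors. All intermediate artifacts are retained in the result.
#'
#' @param table a cohort data.frame with a `label` column
#' @param config a [selection_config()]
#' @param candidates candidate variables; default all variable columns
#' @return list with `auc` (named, direction-free), `flagged`,
#'   `correlation`, `dropped_correlated`, `survivors`, and the
#'   [lasso_select()] fields
#' @export
screen_features <- function(table, config = selection_config(),
                            candidates = cohort_variables(table)) {
  aucs <- vapply(candidates,
                 function(v) univariate_auc(table, v, direction_free = TRUE),
                 0)
  flagged <- names(aucs)[aucs > config$auc_threshold]
  if (!length(flagged)) {
    warning("no variable exceeds the AUC screen; the screen is advisory ",
            "and the penalized fit proceeds on the full candidate set")
  }
  # order-invariant correlation exclusion: repeatedly resolve the strongest
  # remaining pair above the threshold by dropping its lower-AUC member
  keep <- candidates[order(-aucs, candidates)]
  r <- correlation_matrix(table, candidates)
  dropped <- character()
  repeat {
    rr <- abs(r[keep, keep, drop = FALSE]); diag(rr) <- 0
    if (!length(rr) || max(rr) < config$cor_threshold) break
    ij <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    lose <- pair[which.min(aucs[pair])]
    dropped <- c(dropped, lose)
    keep <- setdiff(keep, lose)
  }
  survivors <- candidates[candidates %in% keep]
  sel <- lasso_select(table, survivors, config)
  c(list(auc = aucs, flagged = flagged, correlation = r,
         dropped_correlated = dropped, survivors = survivors), sel)
}

#' Serialize a selection result as JSON
#'
#' @param result output of [screen_features()] or [lasso_select()]
#' @param path file to write; NULL returns the string
#' @return JSON string, invisibly when written
#' @export
selection_json <- function(result, path = NULL) {
  out <- list(auc = as.list(result$auc),
              flagged = result$flagged,
              dropped_correlated = result$dropped_correlated,
              survivors = result$survivors,
              selected = result$selected,
              lambda = result$lambda,
              coefficients = as.list(result$coefficients))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
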