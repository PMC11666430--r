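#' Cohort table input, encoding, imputation and normalization
#'
#' A cohort table is a plain `data.frame` with one row per subject: a
#' `subject_id` column, a binary `label` column (0 = psoriasis only, 1 =
#' psoriatic arthritis), an optional `cohort` tag, and one numeric column per
#' clinical or serological variable (counts in 10^9/L, percentages in %, CRP
#' in mg/dL, albumin in g/dL). These functions cover loading such tables from
#' CSV, encoding the documented categorical vocabularies to numeric codes,
#' chained random-forest imputation of missing cells, and min-max
#' normalization with strict train/apply separation.
#'
#' @name cohort_io
NULL

# Reserved (non-variable) column names in a cohort table.
.reserved_cols <- c("subject_id", "label", "cohort")

#' Variable columns of a cohort table
#' @param table a cohort data.frame
#' @return character vector of variable column names
#' @export
cohort_variables <- function(table) {
  setdiff(names(table), .reserved_cols)
}

#' Load a cohort table from CSV
#'
#' Reads a CSV with one header row containing a `label` column and the
#' declared schema variables. Unknown columns are dropped with a warning;
#' empty cells become `NA` (missingness is preserved for the imputation
#' stage).
#'
#' @param path path to a CSV file
#' @param schema character vector of expected variable column names
#' @return a cohort `data.frame`
#' @export
load_cohort <- function(path, schema) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!"label" %in% names(raw)) {
    stop("schema error: CSV at '", path, "' has no 'label' column")
  }
  missing_vars <- setdiff(schema, names(raw))
  if (length(missing_vars)) {
    stop("schema error: CSV is missing declared variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  unknown <- setdiff(names(raw), c(.reserved_cols, schema))
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  if (anyNA(raw$label) || !all(raw$label %in% c(0, 1))) {
    stop("schema error: 'label' must be 0/1 and never missing")
  }
  # numeric coercion with cell-level diagnostics; character columns holding
  # categorical vocabularies are left for encode_categories()
  for (v in schema) {
    col <- raw[[v]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) && all(grepl("^[-+0-9.eE ]*$", col[bad]))) {
        stop("parse error: non-numeric cell in numeric column '", v,
             "', row ", bad[1])
      }
      if (!length(bad)) raw[[v]] <- num
    }
  }
  if (!"subject_id" %in% names(raw)) raw$subject_id <- seq_len(nrow(raw))
  raw[c(intersect(.reserved_cols, names(raw)),
        setdiff(names(raw), .reserved_cols))]
}

#' Codebook for the documented categorical vocabularies
#'
#' Sex is coded male = 1, female = 0; yes/no comorbidity variables are coded
#' yes = 1, no = 0; race/ethnicity is coded 1-5 (Mexican American, Other
#' Hispanic, Non-Hispanic White, Non-Hispanic Black, Other); psoriasis rash
#' extent is ordinal 1-4 from "little or no" to "extensive"; education is
#' ordinal 1-5.
#'
#' @return named list mapping variable class to a named code vector
#' @export
category_codebook <- function() {
  list(
    sex = c(male = 1, female = 0),
    yesno = c(yes = 1, no = 0),
    race = c("Mexican American" = 1, "Other Hispanic" = 2,
             "Non-Hispanic White" = 3, "Non-Hispanic Black" = 4,
             "Other" = 5),
    rash_range = c("Little or no psoriasis" = 1, "Only a few patches" = 2,
                   "Scattered patches" = 3, "Extensive psoriasis" = 4),
    education = c("Did not graduate from junior high school" = 1,
                  "Did not graduate high school" = 2,
                  "High school graduate" = 3,
                  "Some college" = 4,
                  "College graduate" = 5)
  )
}

# which codebook entry applies to a variable name
.codebook_class <- function(variable) {
  v <- tolower(variable)
  if (v %in% c("gender", "sex")) return("sex")
  if (v %in% c("race", "race_ethnicity", "ethnicity")) return("race")
  if (v %in% c("rash_range", "rash")) return("rash_range")
  if (v %in% c("education")) return("education")
  "yesno"
}

#' Encode categorical columns to numeric codes
#'
#' Character columns are mapped through [category_codebook()]. An
#' unrecognized token is an error naming both the token and the variable.
#'
#' @param table a cohort data.frame possibly holding character columns
#' @return the table with all variable columns numeric
#' @export
encode_categories <- function(table) {
  book <- category_codebook()
  for (v in cohort_variables(table)) {
    col <- table[[v]]
    if (!is.character(col)) next
    map <- book[[.codebook_class(v)]]
    keys <- names(map)
    idx <- match(trimws(col), keys)
    lowered <- is.na(idx) & !is.na(col)
    idx[lowered] <- match(tolower(trimws(col[lowered])), tolower(keys))
    bad <- !is.na(col) & is.na(idx)
    if (any(bad)) {
      stop("value error: unknown category token '", col[which(bad)[1]],
           "' in variable '", v, "'")
    }
    table[[v]] <- unname(map[idx])
  }
  table
}

#' Decode numeric codes back to category tokens
#'
#' Inverse of [encode_categories()] on the documented vocabularies; used to
#' verify that encoding is a bijection.
#'
#' @param codes numeric code vector
#' @param variable variable name (selects the vocabulary)
#' @return character vector of tokens
#' @export
decode_categories <- function(codes, variable) {
  map <- category_codebook()[[.codebook_class(variable)]]
  idx <- match(codes, unname(map))
  if (anyNA(idx[!is.na(codes)])) {
    stop("value error: code outside the vocabulary of '", variable, "'")
  }
  names(map)[idx]
}

#' Impute missing cells by chained random-forest regression
#'
#' Subjects missing more than one third of their variable columns are dropped
#' (mirroring the cohort exclusion rule) with a logged count. Remaining
#' missing cells are filled by iterative chained imputation: each incomplete
#' variable is regressed on all others with a random forest, fitted on the
#' originally observed rows, and the cycle repeats until the relative change
#' in imputed values falls below `tol` or `max_iter` cycles. Observed cells
#' are never altered and the result is deterministic given `seed`.
#'
#' @param table a cohort data.frame with numeric variable columns
#' @param seed integer seed
#' @param tol relative-change convergence tolerance between cycles
#' @param max_iter maximum number of imputation cycles
#' @param ntree trees per forest
#' @return the table with no missing values among retained subjects
#' @export
impute_missing <- function(table, seed, tol = 1e-3, max_iter = 10,
                           ntree = 100) {
  vars <- cohort_variables(table)
  vm <- as.matrix(table[vars])
  frac_missing <- rowMeans(is.na(vm))
  drop <- frac_missing > 1 / 3
  if (any(drop)) {
    message("dropping ", sum(drop),
            " subject(s) exceeding 1/3 missing data")
    table <- table[!drop, , drop = FALSE]
    vm <- vm[!drop, , drop = FALSE]
  }
  all_missing <- vars[colSums(!is.na(vm)) == 0]
  if (length(all_missing)) {
    stop("variable(s) entirely missing: ",
         paste(all_missing, collapse = ", "))
  }
  miss <- is.na(vm)
  if (!any(miss)) return(table)

  set.seed(as.integer(seed))
  # median start, then chained forests in increasing-missingness order
  filled <- vm
  for (j in seq_along(vars)) {
    if (any(miss[, j])) {
      filled[miss[, j], j] <- stats::median(vm[, j], na.rm = TRUE)
    }
  }
  incomplete <- order(colSums(miss))
  incomplete <- incomplete[colSums(miss)[incomplete] > 0]
  prev <- filled
  for (iter in seq_len(max_iter)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      x <- filled[, -j, drop = FALSE]
      fit <- randomForest::randomForest(x[obs, , drop = FALSE],
                                        y = filled[obs, j], ntree = ntree)
      pred <- stats::predict(fit, x[!obs, , drop = FALSE])
      rng <- range(vm[obs, j])
      filled[!obs, j] <- pmin(pmax(pred, rng[1]), rng[2])
    }
    delta <- sum((filled[miss] - prev[miss])^2)
    scale <- sum(filled[miss]^2)
    if (scale > 0 && sqrt(delta / scale) < tol) break
    prev <- filled
  }
  table[vars] <- as.data.frame(filled)
  table
}

#' Fit min-max normalization parameters on a training partition
#'
#' @param table a cohort data.frame (the training rows only)
#' @param variables variables to normalize; defaults to all variable columns
#' @return a `data.frame` with columns `variable`, `min`, `max`
#'   (NormalizationParams)
#' @export
fit_minmax <- function(table, variables = cohort_variables(table)) {
  data.frame(
    variable = variables,
    min = vapply(variables, function(v) min(table[[v]], na.rm = TRUE), 0),
    max = vapply(variables, function(v) max(table[[v]], na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Apply min-max normalization E(x) = (x - min)/(max - min)
#'
#' Parameters must come from [fit_minmax()] on a training partition; applied
#' rows may map outside \[0, 1\]. A constant training variable (max = min)
#' maps to 0.
#'
#' @param params NormalizationParams from [fit_minmax()]
#' @param table a cohort data.frame
#' @return the table with listed variables rescaled
#' @export
minmax_normalize <- function(params, table) {
  absent <- setdiff(params$variable, names(table))
  if (length(absent)) {
    stop("variable(s) absent from table: ", paste(absent, collapse = ", "))
  }
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    lo <- params$min[i]; hi <- params$max[i]
    table[[v]] <- if (hi > lo) (table[[v]] - lo) / (hi - lo) else
      rep(0, nrow(table))
  }
  table
}
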