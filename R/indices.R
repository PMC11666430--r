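#' Composite inflammation indices
#'
#' A composite inflammation index is a ratio of products of blood-count,
#' CRP and albumin components, optionally divided by a scale constant, with
#' an orientation saying which direction indicates psoriatic arthritis.
#' The catalogue holds eight published indices (SII, NLR, PLR, LMR, NPR,
#' SIM, PAR, CALLY) plus PSAII, the index developed here:
#' `PSAII = lymphocyte% x CRP / (neutrophil count x eosinophil count x 10)`.
#'
#' @name inflammation_indices
NULL

#' Define a composite index
#'
#' @param name index name
#' @param numerator nonempty character vector of component variables
#' @param denominator character vector of component variables (may be empty)
#' @param scale positive constant multiplying the denominator product
#' @param orientation `"higher"` (higher values indicate PSA) or `"lower"`
#' @param cutoff published decision cutoff, if any
#' @return an `index_definition` object
#' @export
index_definition <- function(name, numerator, denominator = character(),
                             scale = 1,
                             orientation = c("higher", "lower"),
                             cutoff = NA_real_) {
  orientation <- match.arg(orientation)
  if (!length(numerator)) stop("numerator must be nonempty")
  if (length(intersect(numerator, denominator))) {
    stop("numerator and denominator must be disjoint")
  }
  if (scale <= 0) stop("scale must be positive")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, scale = scale,
                 orientation = orientation, cutoff = cutoff),
            class = "index_definition")
}

#' The built-in index catalogue
#'
#' Component names follow the cohort-table vocabulary: counts are absolute
#' (10^9/L), `lymphocyte_pct` is the leukocyte percentage, `crp` is in
#' mg/dL and `albumin` in g/dL. CALLY is oriented so that lower values
#' indicate PSA; all others are higher-indicates-PSA. Published cutoffs:
#' PSAII 18, CALLY 0.61.
#'
#' @return named list of nine [index_definition()] objects
#' @export
index_catalogue <- function() {
  defs <- list(
    index_definition("SII", c("platelet_count", "neutrophil_count"),
                     "lymphocyte_count"),
    index_definition("NLR", "neutrophil_count", "lymphocyte_count"),
    index_definition("PLR", "platelet_count", "lymphocyte_count"),
    index_definition("LMR", "lymphocyte_count", "monocyte_count"),
    index_definition("NPR", "neutrophil_count", "platelet_count"),
    index_definition("SIM", c("monocyte_count", "neutrophil_count"),
                     "lymphocyte_count"),
    index_definition("PAR", "platelet_count", "albumin"),
    index_definition("CALLY", c("albumin", "lymphocyte_count"), "crp",
                     scale = 10, orientation = "lower", cutoff = 0.61),
    index_definition("PSAII", c("lymphocyte_pct", "crp"),
                     c("neutrophil_count", "eosinophil_count"),
                     scale = 10, orientation = "higher", cutoff = 18)
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Compute an index for one subject or a whole cohort
#'
#' Returns `prod(numerator) / (prod(denominator) * scale)`. All components
#' must be present; a zero denominator is an error naming the subject.
#'
#' @param defn an [index_definition()]
#' @param subject named numeric vector, list, or cohort data.frame
#' @return numeric vector of index values
#' @export
compute_index <- function(defn, subject) {
  comp <- c(defn$numerator, defn$denominator)
  if (is.data.frame(subject)) {
    absent <- setdiff(comp, names(subject))
    if (length(absent)) {
      stop("index '", defn$name, "': missing component(s) ",
           paste(absent, collapse = ", "))
    }
    num <- Reduce(`*`, subject[defn$numerator], rep(1, nrow(subject)))
    den <- Reduce(`*`, subject[defn$denominator], rep(1, nrow(subject)))
    den <- den * defn$scale
    if (any(den == 0)) {
      who <- if ("subject_id" %in% names(subject))
        subject$subject_id[which(den == 0)[1]] else which(den == 0)[1]
      stop("index '", defn$name, "': zero denominator for subject ", who)
    }
    return(num / den)
  }
  subject <- unlist(subject)
  if (!all(comp %in% names(subject))) {
    stop("index '", defn$name, "': missing component(s) ",
         paste(setdiff(comp, names(subject)), collapse = ", "))
  }
  den <- prod(subject[defn$denominator]) * defn$scale
  if (den == 0) stop("index '", defn$name, "': zero denominator")
  prod(subject[defn$numerator]) / den
}

#' Score a cohort on a catalogue of indices
#'
#' Appends one column per index to the table.
#'
#' @param table a cohort data.frame
#' @param catalogue list of index definitions; default [index_catalogue()]
#' @return the table with index columns appended
#' @export
score_indices <- function(table, catalogue = index_catalogue()) {
  for (defn in catalogue) table[[defn$name]] <- compute_index(defn, table)
  table
}

#' Classify index values against a cutoff
#'
#' Strict-inequality rule: a higher-indicates-PSA index is positive iff
#' `value > cutoff`; a lower-indicates-PSA index iff `value < cutoff`.
#' Equality with the cutoff classifies negative.
#'
#' @param value numeric vector of index values
#' @param cutoff finite cutoff
#' @param orientation `"higher"` or `"lower"`
#' @return integer vector, 1 = positive (screened as PSA), 0 = negative
#' @export
classify_index <- function(value, cutoff, orientation = c("higher",
                                                          "lower")) {
  orientation <- match.arg(orientation)
  stopifnot(is.finite(cutoff))
  if (orientation == "higher") as.integer(value > cutoff) else
    as.integer(value < cutoff)
}

#' Build an index definition from logistic odds ratios
#'
#' The development rule for PSAII: among the eligible features, those with
#' odds ratio above 1 enter the numerator and those below 1 the denominator;
#' an odds ratio of exactly 1 contributes nothing. Features outside
#' `eligible` (e.g. age, which enters the screening model but not the serum
#' index) are ignored. The result is oriented higher-indicates-PSA.
#'
#' @param ors named numeric vector or list of per-feature odds ratios
#' @param eligible features eligible for the index (the serum features)
#' @param scale scale constant of the resulting index
#' @param name name of the resulting index
#' @return an [index_definition()]
#' @export
construct_index_from_ors <- function(ors, eligible = names(ors), scale = 10,
                                     name = "constructed") {
  ors <- unlist(ors)
  use <- intersect(names(ors), eligible)
  vals <- ors[use]
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("odds ratios must be finite and positive")
  }
  numerator <- use[vals > 1]
  denominator <- use[vals < 1]
  if (!length(numerator)) {
    stop("construction error: no feature with odds ratio > 1; ",
         "index undefined")
  }
  index_definition(name, numerator, denominator, scale = scale,
                   orientation = "higher")
}

#' Export a catalogue as JSON
#'
#' @param catalogue list of index definitions
#' @param path file to write; when NULL the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
catalogue_json <- function(catalogue = index_catalogue(), path = NULL) {
  js <- jsonlite::toJSON(lapply(unname(catalogue), unclass),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
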