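#' @import methods
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical order; this is the row/column order of all scoring matrices
#' shipped with the package.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' KernelMatrix: amino-acid pair similarities for the k-mer kernel
#'
#' A symmetric, strictly positive 20x20 matrix of amino-acid pair
#' similarities, obtained by raising the BLOSUM62 observed joint-frequency
#' matrix element-wise to a positive exponent.  Used by [tcrmatchScore()] and
#' friends.
#'
#' @slot values numeric 20x20 matrix, dimnames [AA_ALPHABET] in both
#'   dimensions.
#' @slot exponent positive real; element-wise power applied to the base
#'   frequency matrix.
#' @slot provenance character tag identifying source matrix and transform.
#'
#' @seealso [buildKernelMatrix()]
#' @export
setClass("KernelMatrix",
  representation(values = "matrix", exponent = "numeric",
                 provenance = "character"))

setValidity("KernelMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || !identical(dim(v), c(20L, 20L)))
    return("'values' must be a numeric 20x20 matrix")
  if (!identical(rownames(v), AA_ALPHABET) ||
      !identical(colnames(v), AA_ALPHABET))
    return("dimnames of 'values' must be the 20 amino-acid codes, alphabetical")
  if (any(v <= 0)) return("all kernel matrix entries must be positive")
  if (max(abs(v - t(v))) > 1e-12) return("'values' must be symmetric")
  if (length(object@exponent) != 1L || object@exponent <= 0)
    return("'exponent' must be a single positive number")
  TRUE
})

#' ReferenceDatabase: receptor groups with known epitope specificities
#'
#' Each receptor group pairs one CDR3beta sequence (optionally a CDR3alpha)
#' with the non-empty set of peptidic epitopes it is known to recognize,
#' plus free-text antigen/organism annotation.  A filter log records the
#' group/epitope counts before and after each assembly step.
#'
#' @slot groups data.frame with columns `group_id`, `cdr3b`, `cdr3a`
#'   (`NA` when absent), `antigen`, `organism`.
#' @slot epitopes named list, one character vector of epitopes per group,
#'   names matching `group_id`.
#' @slot provenance data.frame filter log with columns `step`,
#'   `n_groups`, `n_epitopes`, `detail`.
#'
#' @seealso [readReferenceTSV()], [generateSynthetic()],
#'   [filterSingletonEpitopes()]
#' @export
setClass("ReferenceDatabase",
  representation(groups = "data.frame", epitopes = "list",
                 provenance = "data.frame"))

setValidity("ReferenceDatabase", function(object) {
  g <- object@groups
  need <- c("group_id", "cdr3b", "cdr3a", "antigen", "organism")
  if (!all(need %in% names(g)))
    return(paste("'groups' must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$group_id)) return("group_id values must be unique")
  if (nrow(g) > 0 && (any(is.na(g$cdr3b)) || any(!nzchar(g$cdr3b))))
    return("every group needs a non-empty cdr3b")
  e <- object@epitopes
  if (!identical(sort(names(e)), sort(as.character(g$group_id))))
    return("'epitopes' names must match group_id exactly")
  if (any(vapply(e, length, 1L) == 0L))
    return("every group needs at least one epitope")
  if (any(vapply(e, function(x) any(is.na(x) | !nzchar(x)), TRUE)))
    return("epitopes must be non-empty strings")
  TRUE
})

#' CurveSet: a threshold sweep of pooled precision/recall and ROC points
#'
#' One row per threshold: pooled true/false positive epitope calls,
#' precision, recall, and pair-level TPR/FPR, for a single similarity metric.
#'
#' @slot metric metric token (see [metricTokens()]).
#' @slot orientation `"similarity"` (match means score >= threshold) or
#'   `"distance"` (match means score <= threshold).
#' @slot points data.frame with columns `threshold`, `tp`, `fp`, `calls`,
#'   `precision`, `recall`, `tpr`, `fpr`.
#'
#' @seealso [sweepThresholds()], [partialAUC()]
#' @export
setClass("CurveSet",
  representation(metric = "character", orientation = "character",
                 points = "data.frame"))

setValidity("CurveSet", function(object) {
  if (!object@orientation %in% c("similarity", "distance"))
    return("orientation must be 'similarity' or 'distance'")
  need <- c("threshold", "tp", "fp", "calls", "precision", "recall",
            "tpr", "fpr")
  if (!all(need %in% names(object@points)))
    return(paste("'points' must have columns:", paste(need, collapse = ", ")))
  p <- object@points
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(p$precision) || !ok(p$recall) || !ok(p$tpr) || !ok(p$fpr))
    return("precision/recall/tpr/fpr must lie in [0, 1] (or NA)")
  TRUE
})

#' BootstrapComparison: partial-AUC distributions and p-values vs TCRMatch
#'
#' @slot n_boot number of bootstrap resamples.
#' @slot pauc data.frame, one row per resample, one column per metric,
#'   holding the partial AUC of the precision-recall curve over the
#'   configured recall window.
#' @slot p_values named numeric; for each rival metric, the fraction of
#'   resamples in which its partial AUC strictly exceeded TCRMatch's.
#' @slot ci data.frame with columns `metric`, `lo`, `hi` (2.5/97.5
#'   percentiles of the pAUC distribution) and `mean`.
#' @slot recall_window numeric length-2, the recall integration window.
#'
#' @seealso [bootstrapCompare()]
#' @export
setClass("BootstrapComparison",
  representation(n_boot = "numeric", pauc = "data.frame",
                 p_values = "numeric", ci = "data.frame",
                 recall_window = "numeric"))

#' @describeIn ReferenceDatabase-class number of receptor groups
#' @param x,object a `ReferenceDatabase`
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("nGroups", "ReferenceDatabase", function(x) nrow(x@groups))

#' @describeIn ReferenceDatabase-class CDR3beta sequences, named by group id
#' @export
setGeneric("cdr3b", function(x) standardGeneric("cdr3b"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("cdr3b", "ReferenceDatabase", function(x)
  stats::setNames(x@groups$cdr3b, x@groups$group_id))

#' @describeIn ReferenceDatabase-class CDR3alpha sequences (`NA` when absent)
#' @export
setGeneric("cdr3a", function(x) standardGeneric("cdr3a"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("cdr3a", "ReferenceDatabase", function(x)
  stats::setNames(x@groups$cdr3a, x@groups$group_id))

#' @describeIn ReferenceDatabase-class per-group epitope sets (named list)
#' @export
setGeneric("epitopeList", function(x) standardGeneric("epitopeList"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("epitopeList", "ReferenceDatabase", function(x)
  x@epitopes[as.character(x@groups$group_id)])

#' @describeIn ReferenceDatabase-class map from epitope to the ids of the
#'   groups recognizing it (derived, always consistent with the groups)
#' @export
setGeneric("epitopeIndex", function(x) standardGeneric("epitopeIndex"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("epitopeIndex", "ReferenceDatabase", function(x) {
  eps <- epitopeList(x)
  if (length(eps) == 0L) return(list())
  ids <- rep(names(eps), lengths(eps))
  split(ids, unlist(eps, use.names = FALSE))
})

#' @describeIn ReferenceDatabase-class the filter log
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("provenance", "ReferenceDatabase", function(x) x@provenance)

#' @describeIn CurveSet-class the per-threshold points as a data.frame
#' @param x,object a `CurveSet`
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname CurveSet-class
#' @export
setMethod("curvePoints", "CurveSet", function(x) x@points)

#' @rdname CurveSet-class
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname CurveSet-class
#' @export
setMethod("metricName", "CurveSet", function(x) x@metric)

#' @rdname CurveSet-class
#' @export
setGeneric("metricOrientation", function(x) standardGeneric("metricOrientation"))

#' @rdname CurveSet-class
#' @export
setMethod("metricOrientation", "CurveSet", function(x) x@orientation)

setMethod("show", "KernelMatrix", function(object) {
  cat("KernelMatrix (", object@provenance, ")\n", sep = "")
  cat("  exponent:", format(object@exponent), "\n")
  cat("  m(A,A) =", format(object@values["A", "A"], digits = 6),
      " m(L,L) =", format(object@values["L", "L"], digits = 6), "\n")
})

setMethod("show", "ReferenceDatabase", function(object) {
  n_epi <- length(epitopeIndex(object))
  cat("ReferenceDatabase with", nGroups(object), "receptor groups and",
      n_epi, "unique epitopes\n")
  if (nGroups(object) > 0) {
    paired <- sum(!is.na(object@groups$cdr3a))
    if (paired > 0) cat("  paired (CDR3a present):", paired, "groups\n")
    mono <- sum(lengths(epitopeList(object)) == 1L)
    cat("  mono-specific groups:", mono,
        sprintf("(%.1f%%)", 100 * mono / nGroups(object)), "\n")
  }
  if (nrow(object@provenance) > 0) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(object@provenance)))
      cat(sprintf("    %s: %d groups, %d epitopes%s\n",
                  object@provenance$step[i], object@provenance$n_groups[i],
                  object@provenance$n_epitopes[i],
                  ifelse(nzchar(object@provenance$detail[i]),
                         paste0(" (", object@provenance$detail[i], ")"), "")))
  }
})

setMethod("show", "CurveSet", function(object) {
  cat("CurveSet:", object@metric, "(", object@orientation, "),",
      nrow(object@points), "thresholds\n")
  r <- range(object@points$threshold)
  cat("  threshold range:", format(r[1], digits = 4), "-",
      format(r[2], digits = 4), "\n")
})

setMethod("show", "BootstrapComparison", function(object) {
  cat("BootstrapComparison:", object@n_boot, "resamples, recall window",
      object@recall_window[1], "-", object@recall_window[2], "\n")
  print(object@ci, row.names = FALSE)
  if (length(object@p_values)) {
    cat("  p-values vs tcrmatch:\n")
    for (m in names(object@p_values))
      cat(sprintf("    %s: %.3f\n", m, object@p_values[[m]]))
  }
})

# internal constructor keeping slots consistent
.newReferenceDatabase <- function(groups, epitopes, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(step = character(), n_groups = integer(),
                             n_epitopes = integer(), detail = character(),
                             stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  new("ReferenceDatabase", groups = groups,
      epitopes = epitopes[as.character(groups$group_id)],
      provenance = provenance)
}

.logStep <- function(db, step, detail = "") {
  p <- rbind(db@provenance,
             data.frame(step = step, n_groups = nGroups(db),
                        n_epitopes = length(epitopeIndex(db)),
                        detail = detail, stringsAsFactors = FALSE))
  db@provenance <- p
  db
}
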