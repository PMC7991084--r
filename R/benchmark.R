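# Evaluation engine: match calling, pooled precision/recall, ROC points,
# threshold sweeps, partial AUC of the precision-recall curve, and paired
# chain score averaging.
#
# TP/FP accounting (micro-pooled): every matched reference group contributes
# one epitope call per epitope it recognizes; a call is a TP if the query
# also recognizes that epitope, else an FP.  Duplicate calls across multiple
# matches count separately.  Recall is the fraction of (query, epitope)
# pairs for which at least one match recognizes the epitope.  TPR/FPR are
# pair-level: an ordered (query, reference) comparison is a positive iff the
# two groups share at least one epitope.

#' A receptor group literal
#'
#' Convenience constructor for a single query group.
#'
#' @param cdr3b CDR3beta sequence.
#' @param epitopes character vector of recognized epitopes.
#' @param group_id optional id (used for self-exclusion when benchmarking a
#'   database against itself).
#' @param cdr3a optional CDR3alpha.
#' @return list usable wherever a query group is expected.
#' @export
receptorGroup <- function(cdr3b, epitopes, group_id = NA_character_,
                          cdr3a = NA_character_) {
  stopifnot(length(epitopes) >= 1L)
  list(group_id = as.character(group_id), cdr3b = cdr3b, cdr3a = cdr3a,
       epitopes = unique(as.character(epitopes)))
}

# normalize queries (a ReferenceDatabase or a list of receptorGroup lists)
# to parallel vectors/lists
.asGroups <- function(x, chain = "beta") {
  pick <- function(b, a) if (chain == "alpha") a else b
  if (is(x, "ReferenceDatabase")) {
    seqs <- pick(x@groups$cdr3b, x@groups$cdr3a)
    if (chain == "alpha" && any(is.na(seqs)))
      stop("database has groups without a CDR3alpha")
    return(list(ids = x@groups$group_id, seqs = seqs,
                epitopes = unname(epitopeList(x))))
  }
  if (is.list(x) && !is.null(x$cdr3b)) x <- list(x)
  list(ids = vapply(x, function(g) g$group_id %||% NA_character_, ""),
       seqs = vapply(x, function(g) pick(g$cdr3b, g$cdr3a), ""),
       epitopes = lapply(x, `[[`, "epitopes"))
}

# metric score matrices between query groups and database groups for a chain
# ("beta", "alpha", or "paired" = mean of the two per-chain scores); one NW
# pass is shared across the alignment-derived metrics
.chainScoresAll <- function(metrics, q, db, chain, config) {
  if (chain == "paired") {
    qb <- .asGroups(q, "beta"); qa <- .asGroups(q, "alpha")
    rb <- .asGroups(db, "beta"); ra <- .asGroups(db, "alpha")
    mb <- .metricMatrices(metrics, qb$seqs, rb$seqs, config)
    ma <- .metricMatrices(metrics, qa$seqs, ra$seqs, config)
    stats::setNames(lapply(metrics, function(m) (mb[[m]] + ma[[m]]) / 2),
                    metrics)
  } else {
    .metricMatrices(metrics, .asGroups(q, chain)$seqs,
                    .asGroups(db, chain)$seqs, config)
  }
}

.chainScores <- function(metric, q, db, chain, config) {
  .chainScoresAll(metric, q, db, chain, config)[[1]]
}

.matchedAt <- function(scores, threshold, orientation) {
  if (orientation == "similarity") scores >= threshold else scores <= threshold
}

#' Call database matches for one query group
#'
#' Scores the query against every reference group (excluding any group with
#' the query's own `group_id`), flags matches at the threshold (inclusive:
#' a score equal to the cutoff matches), and partitions each match's
#' epitopes into shared and unshared with the query.
#'
#' @param query a [receptorGroup()].
#' @param db a [ReferenceDatabase-class].
#' @param metric metric token (default `"tcrmatch"`).
#' @param threshold score cutoff on the metric's scale.
#' @param config metric parameters, see [computeMetric()].
#' @return data.frame with one row per reference group: `query_id`,
#'   `group_id`, `metric`, `score`, `matched`, `shared`, `unshared`
#'   (comma-joined epitope strings).
#' @export
callMatches <- function(query, db, metric = "tcrmatch", threshold = 0.97,
                        config = list()) {
  orientation <- metricOrientationOf(metric)
  g <- .asGroups(query)
  S <- .chainScores(metric, query, db, "beta", config)
  ids <- db@groups$group_id
  keep <- is.na(g$ids[1]) | ids != g$ids[1]
  eps <- epitopeList(db)
  qe <- g$epitopes[[1]]
  shared <- vapply(eps, function(e) paste(intersect(e, qe), collapse = ","), "")
  unshared <- vapply(eps, function(e) paste(setdiff(e, qe), collapse = ","), "")
  out <- data.frame(query_id = g$ids[1], group_id = ids,
                    metric = metric, score = as.numeric(S[1, ]),
                    matched = .matchedAt(as.numeric(S[1, ]), threshold,
                                         orientation),
                    shared = shared, unshared = unshared,
                    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Pooled precision and recall from a raw score matrix
#'
#' Low-level entry point taking precomputed scores, so the accounting can be
#' exercised on constructed examples.  Rows are queries, columns reference
#' groups.
#'
#' @param scores numeric matrix of metric scores.
#' @param query_epitopes list of epitope vectors, one per row.
#' @param ref_epitopes list of epitope vectors, one per column.
#' @param threshold score cutoff (inclusive).
#' @param orientation `"similarity"` or `"distance"`.
#' @param exclude optional logical matrix, `TRUE` for comparisons to drop
#'   (e.g. self-comparisons).
#' @return one-row data.frame: `threshold`, `tp`, `fp`, `calls`,
#'   `precision` (NA when there are no calls), `recall`, `tpr`, `fpr`.
#' @export
precisionRecallFromScores <- function(scores, query_epitopes, ref_epitopes,
                                      threshold,
                                      orientation = c("similarity", "distance"),
                                      exclude = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(nrow(scores) == length(query_epitopes),
            ncol(scores) == length(ref_epitopes))
  M <- .matchedAt(scores, threshold, orientation)
  if (!is.null(exclude)) M[exclude] <- FALSE
  valid <- if (is.null(exclude)) matrix(TRUE, nrow(scores), ncol(scores))
           else !exclude
  shared <- matrix(0L, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores)))
    shared[i, ] <- vapply(ref_epitopes, function(e)
      length(intersect(e, query_epitopes[[i]])), 1L)
  tot <- lengths(ref_epitopes)
  callsM <- matrix(tot, nrow(scores), ncol(scores), byrow = TRUE)
  tp <- sum(shared[M]); calls <- sum(callsM[M]); fp <- calls - tp
  # recall over (query, epitope) pairs
  rec_num <- 0L; rec_den <- 0L
  for (i in seq_len(nrow(scores))) {
    for (e in query_epitopes[[i]]) {
      rec_den <- rec_den + 1L
      has <- vapply(ref_epitopes, function(x) e %in% x, TRUE) & M[i, ]
      if (any(has)) rec_num <- rec_num + 1L
    }
  }
  pos <- shared > 0 & valid
  neg <- shared == 0 & valid
  data.frame(threshold = threshold, tp = tp, fp = fp, calls = calls,
             precision = if (calls > 0) tp / calls else NA_real_,
             recall = if (rec_den > 0) rec_num / rec_den else NA_real_,
             tpr = if (sum(pos) > 0) sum(M & pos) / sum(pos) else NA_real_,
             fpr = if (sum(neg) > 0) sum(M & neg) / sum(neg) else NA_real_)
}

#' Pooled precision and recall at one threshold
#'
#' Scores every query against every database group (self-comparisons
#' excluded by `group_id`) and micro-pools TP/FP epitope calls over all
#' matches.
#'
#' @param queries a [ReferenceDatabase-class] (leave-one-out benchmarking)
#'   or a list of [receptorGroup()]s.
#' @param db the reference [ReferenceDatabase-class].
#' @param metric metric token.
#' @param threshold score cutoff (inclusive).
#' @param chain `"beta"` (default), `"alpha"`, or `"paired"` (the two
#'   per-chain scores averaged).
#' @param config metric parameters.
#' @param scores optional precomputed score matrix (queries x database
#'   groups), bypassing internal scoring.
#' @return one-row data.frame as in [precisionRecallFromScores()].
#' @export
precisionRecall <- function(queries, db, metric = "tcrmatch", threshold = 0.97,
                            chain = c("beta", "alpha", "paired"),
                            config = list(), scores = NULL) {
  chain <- match.arg(chain)
  cs <- sweepThresholds(queries, db, metric, thresholds = threshold,
                        chain = chain, config = config, scores = scores)
  cs@points
}

#' ROC point at one threshold
#'
#' Pair-level true/false positive rates: over all ordered (query, reference)
#' comparisons (self excluded), a comparison is a positive iff the two
#' groups share at least one epitope.
#'
#' @inheritParams precisionRecall
#' @return named numeric `c(tpr = , fpr = )` (`fpr` is NA when there are no
#'   negatives).
#' @export
rocPoint <- function(queries, db, metric = "tcrmatch", threshold = 0.97,
                     chain = c("beta", "alpha", "paired"), config = list()) {
  p <- precisionRecall(queries, db, metric, threshold, chain, config)
  c(tpr = p$tpr, fpr = p$fpr)
}

# group x epitope incidence matrix
.incidence <- function(epitopes, all_epi) {
  B <- matrix(FALSE, length(epitopes), length(all_epi))
  if (length(epitopes))
    B[cbind(rep(seq_along(epitopes), lengths(epitopes)),
            match(unlist(epitopes, use.names = FALSE), all_epi))] <- TRUE
  B
}

# Per-row threshold-grid curve components, so one precomputation serves both
# the full sweep (aggregate all rows) and the bootstrap (aggregate resampled
# rows).  grid must be sorted ascending; cutoffs are inclusive.
.rowCurves <- function(S, query_epitopes, ref_epitopes, orientation, grid,
                       exclude = NULL) {
  n <- nrow(S); nt <- length(grid)
  sim <- orientation == "similarity"
  all_epi <- unique(unlist(c(query_epitopes, ref_epitopes),
                           use.names = FALSE))
  qB <- .incidence(query_epitopes, all_epi)
  rB <- .incidence(ref_epitopes, all_epi)
  shared_all <- qB %*% t(rB)          # shared-epitope counts per pair
  tot <- rowSums(rB)
  # best score per (query, epitope): mask excluded comparisons, then take the
  # row-wise extreme over the columns recognizing each epitope
  Sm <- S
  if (!is.null(exclude)) Sm[exclude] <- if (sim) -Inf else Inf
  bestS <- matrix(if (sim) -Inf else Inf, n, length(all_epi))
  for (e in seq_along(all_epi)) {
    cols <- which(rB[, e])
    if (length(cols) == 0L) next
    v <- Sm[, cols[1]]
    for (cc in cols[-1]) v <- if (sim) pmax(v, Sm[, cc]) else pmin(v, Sm[, cc])
    bestS[, e] <- v
  }
  countMatched <- function(s) {
    o <- sort(s)
    if (sim) length(s) - findInterval(grid, o, left.open = TRUE)
    else findInterval(grid, o)
  }
  TP <- matrix(0, n, nt); CALLS <- matrix(0, n, nt)
  MPOS <- matrix(0, n, nt); MNEG <- matrix(0, n, nt); REC <- matrix(0, n, nt)
  nPos <- numeric(n); nNeg <- numeric(n); nEpi <- numeric(n)
  for (i in seq_len(n)) {
    keep <- if (is.null(exclude)) seq_len(ncol(S)) else which(!exclude[i, ])
    s <- S[i, keep]
    shared <- shared_all[i, keep]
    o <- order(s)
    so <- s[o]
    below <- if (sim) findInterval(grid, so, left.open = TRUE)
             else findInterval(grid, so)
    cumAt <- function(w) {
      cw <- c(0, cumsum(w[o]))
      if (sim) sum(w) - cw[below + 1L] else cw[below + 1L]
    }
    TP[i, ] <- cumAt(shared)
    CALLS[i, ] <- cumAt(tot[keep])
    pos <- shared > 0
    MPOS[i, ] <- cumAt(as.numeric(pos))
    MNEG[i, ] <- cumAt(as.numeric(!pos))
    nPos[i] <- sum(pos); nNeg[i] <- sum(!pos)
    nEpi[i] <- sum(qB[i, ])
    best <- bestS[i, qB[i, ]]
    REC[i, ] <- countMatched(best[is.finite(best)])
  }
  list(grid = grid, TP = TP, CALLS = CALLS, MPOS = MPOS, MNEG = MNEG,
       REC = REC, nPos = nPos, nNeg = nNeg, nEpi = nEpi)
}

.aggregateCurve <- function(cd, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cd$TP))
  cs <- function(M) colSums(M[rows, , drop = FALSE])
  tp <- cs(cd$TP); calls <- cs(cd$CALLS); fp <- calls - tp
  npos <- sum(cd$nPos[rows]); nneg <- sum(cd$nNeg[rows])
  data.frame(threshold = cd$grid, tp = tp, fp = fp, calls = calls,
             precision = ifelse(calls > 0, tp / calls, NA_real_),
             recall = cs(cd$REC) / sum(cd$nEpi[rows]),
             tpr = if (npos > 0) cs(cd$MPOS) / npos else NA_real_,
             fpr = if (nneg > 0) cs(cd$MNEG) / nneg else NA_real_)
}

.defaultGrid <- function(S, metric, exclude = NULL, n_points = 201L) {
  s <- if (is.null(exclude)) as.numeric(S) else as.numeric(S[!exclude])
  r <- range(s, finite = TRUE)
  grid <- seq(r[1], r[2], length.out = n_points)
  if (metric == "tcrmatch") grid <- c(grid, 0.84, 0.90, 0.97)
  sort(unique(grid))
}

#' Threshold sweep: the full precision-recall / ROC curve
#'
#' Computes a [CurveSet-class] of pooled precision/recall and pair-level
#' TPR/FPR over a threshold grid.  The default grid is 201 points spanning
#' the observed score range; for `tcrmatch` the preset cutoffs 0.84, 0.90
#' and 0.97 are always injected.
#'
#' @inheritParams precisionRecall
#' @param thresholds optional sorted numeric grid.
#' @param n_points grid size when `thresholds` is `NULL`.
#' @param scores optional precomputed score matrix.
#' @return a [CurveSet-class].
#' @export
sweepThresholds <- function(queries, db, metric = "tcrmatch",
                            thresholds = NULL,
                            chain = c("beta", "alpha", "paired"),
                            config = list(), n_points = 201L,
                            scores = NULL) {
  chain <- match.arg(chain)
  orientation <- metricOrientationOf(metric)
  q <- .asGroups(queries)
  S <- scores %||% .chainScores(metric, queries, db, chain, config)
  excl <- outer(q$ids, db@groups$group_id, function(a, b) !is.na(a) & a == b)
  if (is.null(thresholds))
    thresholds <- .defaultGrid(S, metric, excl, n_points)
  if (is.unsorted(thresholds)) stop("'thresholds' must be sorted ascending")
  cd <- .rowCurves(S, q$epitopes, unname(epitopeList(db)), orientation,
                   thresholds, exclude = excl)
  new("CurveSet", metric = metric, orientation = orientation,
      points = .aggregateCurve(cd))
}

#' Partial area under the precision-recall curve
#'
#' Trapezoidal integral of precision over recall restricted to
#' `[recall_lo, recall_hi]`, with linear interpolation at the window edges.
#' Points with undefined precision (no calls) are dropped; duplicate recall
#' values are collapsed to their best precision.  If the curve does not
#' reach `recall_hi`, the integral runs to the largest recall attained.  If
#' the smallest attainable recall lies above `recall_lo` (typical for
#' integer-valued metrics, whose recall jumps at the strictest usable
#' cutoff), the precision at that smallest recall is extended as a constant
#' down to the window floor: randomly sub-thresholding inside the strictest
#' tied score block reaches any smaller recall at the same expected
#' precision, so the extension is the expected-precision curve under random
#' tie-breaking (and inert for continuous scores).  `NA` is returned only
#' when the curve never reaches the window floor with a defined precision.
#'
#' @param curve a [CurveSet-class] or a data.frame with `recall` and
#'   `precision` columns.
#' @param recall_lo,recall_hi integration window (default 0 to 0.5).
#' @return the partial AUC (at most `recall_hi - recall_lo`), or `NA` if
#'   the curve has no support inside the window.
#' @export
partialAUC <- function(curve, recall_lo = 0, recall_hi = 0.5) {
  if (recall_lo >= recall_hi) stop("need recall_lo < recall_hi")
  p <- if (is(curve, "CurveSet")) curve@points else curve
  p <- p[!is.na(p$precision) & !is.na(p$recall), c("recall", "precision")]
  if (nrow(p) == 0L) return(NA_real_)
  p <- stats::aggregate(precision ~ recall, data = p, FUN = max)
  p <- p[order(p$recall), ]
  x <- p$recall; y <- p$precision
  if (max(x) <= recall_lo) return(NA_real_)
  if (x[1] > recall_lo) {
    x <- c(recall_lo, x)
    y <- c(y[1], y)
  }
  interp <- function(x0) stats::approx(x, y, xout = x0, ties = max,
                                       rule = 2)$y
  lo <- max(recall_lo, min(x)); hi <- min(recall_hi, max(x))
  if (lo >= hi) return(NA_real_)
  inside <- x > lo & x < hi
  xx <- c(lo, x[inside], hi)
  yy <- c(interp(lo), y[inside], interp(hi))
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Paired-chain score averaging
#'
#' Compares CDR3alpha to CDR3alpha and CDR3beta to CDR3beta with the same
#' metric and averages the two scores; orientation is inherited.
#'
#' @param metric metric token.
#' @param alpha1,beta1 chains of the first TCR.
#' @param alpha2,beta2 chains of the second TCR.
#' @param config metric parameters.
#' @return one-row data.frame with `metric`, `value`, `orientation`.
#' @export
pairedScore <- function(metric, alpha1, beta1, alpha2, beta2,
                        config = list()) {
  a <- computeMetric(metric, alpha1, alpha2, config)
  b <- computeMetric(metric, beta1, beta2, config)
  .metricResult(metric, (a$value + b$value) / 2)
}
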