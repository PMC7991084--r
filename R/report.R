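# Reporting helpers: the percentage/ratio arithmetic used in summaries and
# the benchmark report files (TSV of curve points, JSON summary).

#' Percentage of a count
#'
#' `round(100 * numerator / denominator, digits)`, the convention used for
#' dataset composition summaries (e.g. the share of mono-specific receptor
#' groups).
#'
#' @param numerator,denominator counts.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @examples
#' percentOf(21851, 24678)  # 88.5
#' @export
percentOf <- function(numerator, denominator, digits = 1) {
  if (any(denominator == 0)) stop("denominator must be non-zero")
  round(100 * numerator / denominator, digits)
}

#' Ratio of two counts
#'
#' `round(numerator / denominator, digits)`; used e.g. for the uniform-null
#' expected baseline precision 1 / (number of epitopes).
#'
#' @inheritParams percentOf
#' @param digits decimal places (default 3).
#' @return numeric ratio.
#' @export
ratioOf <- function(numerator, denominator, digits = 3) {
  if (any(denominator == 0)) stop("denominator must be non-zero")
  round(numerator / denominator, digits)
}

#' Write a benchmark report
#'
#' Writes the per-metric curve points as one TSV and a JSON summary with
#' partial AUCs (and bootstrap CIs / p-values when supplied).  No
#' timestamps are written, so output files are stable under re-runs.
#'
#' @param curves named list of [CurveSet-class] objects (names = metric
#'   tokens).
#' @param path_prefix output path prefix; writes `<prefix>_curves.tsv` and
#'   `<prefix>_summary.json`.
#' @param boot optional [BootstrapComparison-class].
#' @param recall_lo,recall_hi pAUC window for the summary.
#' @return named character vector of the two file paths, invisibly.
#' @export
writeBenchmarkReport <- function(curves, path_prefix, boot = NULL,
                                 recall_lo = 0, recall_hi = 0.5) {
  pts <- do.call(rbind, lapply(names(curves), function(m) {
    p <- curvePoints(curves[[m]])
    cbind(data.frame(metric = m, stringsAsFactors = FALSE), p)
  }))
  tsv <- paste0(path_prefix, "_curves.tsv")
  utils::write.table(format(pts, digits = 6, trim = TRUE), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    recall_window = c(recall_lo, recall_hi),
    pauc = lapply(curves, partialAUC, recall_lo = recall_lo,
                  recall_hi = recall_hi))
  if (!is.null(boot)) {
    summary$bootstrap <- list(n_boot = boot@n_boot,
                              p_values = as.list(boot@p_values),
                              ci = boot@ci)
  }
  json <- paste0(path_prefix, "_summary.json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(curves = tsv, summary = json))
}
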