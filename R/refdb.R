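# Reference-database model and I/O: the bespoke TSV dialect, the dataset
# assembly filters, the shuffled chance control, and paired-chain assembly.

#' Construct a ReferenceDatabase from vectors
#'
#' Records sharing an identical CDR3beta are merged into one receptor group
#' with the union of their epitopes (annotation: first non-missing value
#' wins) when `merge = TRUE`.  Sequences are assumed already trimmed and
#' valid; use [readReferenceTSV()] for raw files.
#'
#' @param cdr3b character vector of CDR3beta sequences.
#' @param epitopes list of character vectors, one per record.
#' @param cdr3a optional CDR3alpha sequences (`NA` where absent).
#' @param antigen,organism optional annotation.
#' @param group_id optional stable ids; autogenerated as `G1..Gn` post-merge.
#' @param merge merge identical CDR3beta records (default `TRUE`).
#' @return a [ReferenceDatabase-class].
#' @export
referenceDatabase <- function(cdr3b, epitopes, cdr3a = NA_character_,
                              antigen = NA_character_,
                              organism = NA_character_, group_id = NULL,
                              merge = TRUE) {
  n <- length(cdr3b)
  stopifnot(length(epitopes) == n)
  cdr3a <- rep_len(as.character(cdr3a), n)
  antigen <- rep_len(as.character(antigen), n)
  organism <- rep_len(as.character(organism), n)
  epitopes <- lapply(epitopes, function(e) unique(as.character(e)))
  if (merge && n > 0 && anyDuplicated(cdr3b)) {
    key <- match(cdr3b, unique(cdr3b))
    firstOf <- function(x) {
      v <- x[!is.na(x)]
      if (length(v)) v[1] else NA_character_
    }
    epitopes <- lapply(split(seq_len(n), key),
                       function(i) unique(unlist(epitopes[i])))
    cdr3a <- vapply(split(cdr3a, key), firstOf, "")
    antigen <- vapply(split(antigen, key), firstOf, "")
    organism <- vapply(split(organism, key), firstOf, "")
    cdr3b <- unique(cdr3b)
    group_id <- NULL
    n <- length(cdr3b)
  }
  if (is.null(group_id))
    group_id <- if (n == 0L) character(0) else paste0("G", seq_len(n))
  group_id <- as.character(group_id)
  groups <- data.frame(group_id = group_id, cdr3b = cdr3b, cdr3a = cdr3a,
                       antigen = antigen, organism = organism,
                       stringsAsFactors = FALSE)
  .newReferenceDatabase(groups, stats::setNames(epitopes, group_id))
}

#' Read a reference database TSV
#'
#' Dialect: UTF-8, tab-separated, header with at least `cdr3b` and
#' `epitopes` (comma-separated within the cell); optional `group_id`,
#' `cdr3a`, `antigen`, `organism`.  Rows lacking a CDR3beta or at least one
#' epitope are skipped and counted; CDR3 sequences are flank-trimmed (see
#' [trimFlanks()]) and validated, with unusable rows skipped per-row rather
#' than fatal.  Identical CDR3beta records are merged into one group with
#' the union of epitopes.
#'
#' @param path file path.
#' @param merge merge identical CDR3beta records (default `TRUE`).
#' @return a [ReferenceDatabase-class] with a provenance log.
#' @export
readReferenceTSV <- function(path, merge = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           check.names = TRUE)
  if (!all(c("cdr3b", "epitopes") %in% names(raw)))
    stop("reference TSV must have 'cdr3b' and 'epitopes' columns")
  for (col in c("cdr3a", "antigen", "organism"))
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  n_in <- nrow(raw)
  blank2na <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  }
  raw$epitopes <- as.character(raw$epitopes)
  raw$epitopes[is.na(raw$epitopes)] <- ""
  raw$cdr3b <- blank2na(raw$cdr3b)
  raw$cdr3a <- blank2na(raw$cdr3a)
  epi <- lapply(strsplit(raw$epitopes, ","),
                function(e) unique(trimws(e)[nzchar(trimws(e))]))
  missing_core <- is.na(raw$cdr3b) | lengths(epi) == 0L
  keep <- !missing_core
  n_missing <- sum(missing_core)

  trimOne <- function(x) {
    if (is.na(x)) return(NA_character_)
    rep <- tryCatch(trimFlanks(x), error = function(e) NULL)
    if (is.null(rep) || rep$rejected) return(NA_character_)
    ok <- tryCatch(validateCDR3(rep$trimmed), error = function(e) NULL)
    if (is.null(ok)) NA_character_ else ok
  }
  raw$cdr3b[keep] <- vapply(raw$cdr3b[keep], trimOne, "")
  raw$cdr3a[keep] <- vapply(raw$cdr3a[keep], trimOne, "")
  bad_seq <- keep & is.na(raw$cdr3b)
  n_bad <- sum(bad_seq)
  if (n_bad > 0)
    warning(n_bad, " row(s) skipped: CDR3beta unusable after trimming")
  keep <- keep & !bad_seq

  db <- referenceDatabase(raw$cdr3b[keep], epi[keep], raw$cdr3a[keep],
                          blank2na(raw$antigen)[keep],
                          blank2na(raw$organism)[keep], merge = merge)
  db@provenance <- data.frame(
    step = "read_reference_tsv", n_groups = nGroups(db),
    n_epitopes = length(epitopeIndex(db)),
    detail = sprintf("%d rows read, %d lacking cdr3b/epitope, %d invalid",
                     n_in, n_missing, n_bad),
    stringsAsFactors = FALSE)
  db
}

#' Write a reference database TSV
#'
#' Inverse of [readReferenceTSV()] (sequences are written as stored, i.e.
#' already trimmed, so the round trip is lossless).
#'
#' @param db a [ReferenceDatabase-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceTSV <- function(db, path) {
  g <- db@groups
  out <- data.frame(group_id = g$group_id, cdr3b = g$cdr3b,
                    cdr3a = ifelse(is.na(g$cdr3a), "", g$cdr3a),
                    epitopes = vapply(epitopeList(db), paste, "",
                                      collapse = ","),
                    antigen = ifelse(is.na(g$antigen), "", g$antigen),
                    organism = ifelse(is.na(g$organism), "", g$organism),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read query CDR3 sequences
#'
#' Plain text (one sequence per line, blank lines ignored) or AIRR
#' Rearrangement TSV (the `junction_aa` column).
#'
#' @param path file path.
#' @param format `"lines"` or `"airr"`.
#' @return character vector of raw sequences (untrimmed).
#' @export
readQueries <- function(path, format = c("lines", "airr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "lines") {
    x <- trimws(readLines(path, warn = FALSE))
    return(x[nzchar(x)])
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (!"junction_aa" %in% names(tab))
    stop("AIRR TSV lacks the 'junction_aa' column")
  x <- trimws(tab$junction_aa)
  x[!is.na(x) & nzchar(x)]
}

#' Remove singleton epitopes
#'
#' Removes every epitope recognized by exactly one receptor group, then
#' removes groups left without epitopes.  Because removing a group can
#' create new singleton epitopes, the filter iterates to a fixpoint, which
#' guarantees the stated invariant: every remaining epitope is recognized by
#' at least two groups.
#'
#' @param db a [ReferenceDatabase-class].
#' @return the filtered database, with provenance updated.
#' @export
filterSingletonEpitopes <- function(db) {
  g <- db@groups
  eps <- epitopeList(db)
  n_epi_before <- length(unique(unlist(eps, use.names = FALSE)))
  repeat {
    idx <- table(unlist(eps, use.names = FALSE))
    singletons <- names(idx)[idx == 1L]
    if (length(singletons) == 0L) break
    eps <- lapply(eps, setdiff, y = singletons)
    keep <- lengths(eps) > 0L
    eps <- eps[keep]
    g <- g[keep, , drop = FALSE]
  }
  out <- .newReferenceDatabase(g, eps, db@provenance)
  .logStep(out, "filter_singleton_epitopes",
           sprintf("removed %d epitopes, %d groups",
                   n_epi_before - length(epitopeIndex(out)),
                   nrow(db@groups) - nrow(g)))
}

#' Shuffled chance control
#'
#' Returns a database with the same receptor groups and the same multiset of
#' epitope calls, but with the pairing between groups and epitope calls
#' permuted uniformly at random; each group keeps its epitope count.
#' Duplicate epitopes landing in one group are repaired by deterministic
#' swapping.  Estimates the chance level of shared-epitope matches.
#'
#' @param db a [ReferenceDatabase-class].
#' @param seed integer seed; the result is bit-identical across runs for a
#'   fixed seed.
#' @return a [ReferenceDatabase-class].
#' @export
shuffleControl <- function(db, seed = 1L) {
  eps <- epitopeList(db)
  sizes <- lengths(eps)
  calls <- unlist(eps, use.names = FALSE)
  if (length(calls) == 0L) return(db)
  set.seed(as.integer(seed))
  perm <- sample(calls)
  idx <- rep(seq_along(sizes), sizes)
  slots <- split(seq_along(perm), idx)
  # repair within-group duplicates by swapping with a compatible slot
  for (gi in seq_along(slots)) {
    s <- slots[[gi]]
    repeat {
      dup <- s[duplicated(perm[s])]
      if (length(dup) == 0L) break
      p <- dup[1]
      done <- FALSE
      for (q in sample(seq_along(perm))) {
        if (idx[q] == gi) next
        tgt <- slots[[idx[q]]]
        if (perm[q] %in% perm[s]) next                 # would not fix
        if (perm[p] %in% perm[setdiff(tgt, q)]) next   # would create a dup
        tmp <- perm[p]; perm[p] <- perm[q]; perm[q] <- tmp
        done <- TRUE
        break
      }
      if (!done) stop("shuffle repair failed; epitope multiset too degenerate")
    }
  }
  shuffled <- split(perm, idx)
  out <- db
  out@epitopes <- stats::setNames(shuffled, names(eps))
  .logStep(out, "shuffle_control", sprintf("seed %d", as.integer(seed)))
}

#' Assemble the paired-chain database
#'
#' Keeps only groups with both chains, drops every group whose CDR3alpha or
#' CDR3beta occurs in more than one group (all occurrences removed, so the
#' result has all-unique chains), then applies [filterSingletonEpitopes()].
#'
#' @param db a [ReferenceDatabase-class].
#' @return the filtered database, with each step logged in provenance.
#' @export
assemblePaired <- function(db) {
  g <- db@groups
  eps <- epitopeList(db)
  keep <- !is.na(g$cdr3a)
  g <- g[keep, , drop = FALSE]; eps <- eps[keep]
  out <- .newReferenceDatabase(g, eps, db@provenance)
  out <- .logStep(out, "paired_both_chains",
                  sprintf("dropped %d single-chain groups", sum(!keep)))
  dupb <- g$cdr3b %in% g$cdr3b[duplicated(g$cdr3b)]
  dupa <- g$cdr3a %in% g$cdr3a[duplicated(g$cdr3a)]
  keep <- !(dupb | dupa)
  g <- g[keep, , drop = FALSE]; eps <- eps[keep]
  out <- .newReferenceDatabase(g, eps, out@provenance)
  out <- .logStep(out, "paired_unique_chains",
                  sprintf("dropped %d groups sharing a chain", sum(!keep)))
  filterSingletonEpitopes(out)
}
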