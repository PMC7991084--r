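# Independent oracles: literal enumerations and quadratic DPs, kept free of
# the package's fast paths so the two routes can be compared.

randomCDR3 <- function(n, min_len = 3, max_len = 18, alphabet = AA_ALPHABET) {
  vapply(sample(seq(min_len, max_len), n, replace = TRUE), function(len)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

# brute-force k-mer kernel: literally enumerate every k-mer pair
oracleKernelRaw <- function(s1, s2, M) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  total <- 0
  for (k in seq_len(min(length(a), length(b)))) {
    for (i in seq_len(length(a) - k + 1)) {
      for (j in seq_len(length(b) - k + 1)) {
        prod <- 1
        for (p in 0:(k - 1)) prod <- prod * M[a[i + p], b[j + p]]
        total <- total + prod
      }
    }
  }
  total
}

# quadratic DP edit distance
oracleLevenshtein <- function(s, t) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b))
    d[i + 1, j + 1] <- min(d[i, j] + (a[i] != b[j]),
                           d[i, j + 1] + 1, d[i + 1, j] + 1)
  d[length(a) + 1, length(b) + 1]
}

# enumerate every global alignment of two short sequences as a list of
# column pairs (i, j), 0 meaning a gap in that sequence
enumerateAlignments <- function(n, m) {
  rec <- function(i, j) {
    if (i == n && j == m) return(list(list()))
    out <- list()
    if (i < n && j < m)
      out <- c(out, lapply(rec(i + 1, j + 1), function(al)
        c(list(c(i + 1, j + 1)), al)))
    if (i < n)
      out <- c(out, lapply(rec(i + 1, j), function(al)
        c(list(c(i + 1, 0)), al)))
    if (j < m)
      out <- c(out, lapply(rec(i, j + 1), function(al)
        c(list(c(0, j + 1)), al)))
    out
  }
  rec(0, 0)
}

# affine-gap score of one explicit alignment (gap of length L costs
# open + (L - 1) * extend; penalties passed as positive numbers)
scoreAlignmentAffine <- function(al, a, b, sub, open, extend) {
  score <- 0
  gap1 <- FALSE; gap2 <- FALSE
  for (col in al) {
    if (col[1] > 0 && col[2] > 0) {
      score <- score + sub[a[col[1]], b[col[2]]]
      gap1 <- gap2 <- FALSE
    } else if (col[1] > 0) {            # gap in sequence 2
      score <- score - if (gap2) extend else open
      gap2 <- TRUE; gap1 <- FALSE
    } else {                            # gap in sequence 1
      score <- score - if (gap1) extend else open
      gap1 <- TRUE; gap2 <- FALSE
    }
  }
  score
}

# optimal NW score by exhaustive enumeration
oracleNWScore <- function(s, t, sub, open, extend) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  als <- enumerateAlignments(length(a), length(b))
  max(vapply(als, scoreAlignmentAffine, 0, a = a, b = b, sub = sub,
             open = open, extend = extend))
}

# minimum TCRdist over all global alignments (linear per-gap-column cost)
oracleTCRdist <- function(s, t, sub, cap = 4, gap = 4) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  colCost <- function(col) {
    if (col[1] > 0 && col[2] > 0) {
      x <- a[col[1]]; y <- b[col[2]]
      if (x == y) 0 else max(0, min(cap, cap - sub[x, y]))
    } else gap
  }
  als <- enumerateAlignments(length(a), length(b))
  min(vapply(als, function(al) sum(vapply(al, colCost, 0)), 0))
}

# direct re-count of pooled precision / recall / rates by explicit loops
oraclePR <- function(S, qeps, reps, threshold, orientation,
                     exclude = NULL) {
  tp <- 0; calls <- 0; rec_num <- 0; rec_den <- 0
  mpos <- 0; mneg <- 0; npos <- 0; nneg <- 0
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      if (!is.null(exclude) && exclude[i, j]) next
      sh <- length(intersect(qeps[[i]], reps[[j]]))
      if (sh > 0) npos <- npos + 1 else nneg <- nneg + 1
      hit <- if (orientation == "similarity") S[i, j] >= threshold
             else S[i, j] <= threshold
      if (hit) {
        tp <- tp + sh
        calls <- calls + length(reps[[j]])
        if (sh > 0) mpos <- mpos + 1 else mneg <- mneg + 1
      }
    }
    for (e in qeps[[i]]) {
      rec_den <- rec_den + 1
      found <- FALSE
      for (j in seq_len(ncol(S))) {
        if (!is.null(exclude) && exclude[i, j]) next
        hit <- if (orientation == "similarity") S[i, j] >= threshold
               else S[i, j] <= threshold
        if (hit && e %in% reps[[j]]) { found <- TRUE; break }
      }
      if (found) rec_num <- rec_num + 1
    }
  }
  list(tp = tp, fp = calls - tp,
       precision = if (calls > 0) tp / calls else NA_real_,
       recall = rec_num / rec_den,
       tpr = if (npos > 0) mpos / npos else NA_real_,
       fpr = if (nneg > 0) mneg / nneg else NA_real_)
}
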