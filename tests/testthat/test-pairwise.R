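# The six comparison metrics and the uniform dispatch layer.

test_that("global alignment reproduces known cases", {
  B <- blosum62LogOdds()
  a <- globalAlign("CASS", "CASS")
  expect_equal(a$n_columns, 4)
  expect_equal(a$n_identity, 4)
  expect_false(grepl("-", a$aligned1))
  expect_equal(a$score, sum(diag(B[c("C", "A", "S", "S"),
                                   c("C", "A", "S", "S")])))

  a <- globalAlign("CAS", "CASSL")
  expect_equal(a$n_columns, 5)
  expect_equal(a$n_identity, 3)
  # one gap of length 2 under the -7/-1 regime costs 8
  expect_equal(a$score, B["C", "C"] + B["A", "A"] + B["S", "S"] - 8)

  set.seed(5)
  for (s in randomCDR3(20, 3, 15)) {
    res <- globalAlign(s, s)
    ch <- strsplit(s, "")[[1]]
    expect_equal(res$score, sum(B[cbind(ch, ch)]))
    expect_equal(res$n_identity, nchar(s))
  }
})

test_that("alignment score equals exhaustive enumeration on small pairs", {
  B <- blosum62LogOdds()
  set.seed(8)
  for (i in 1:30) {
    s <- randomCDR3(1, 1, 4); t <- randomCDR3(1, 1, 4)
    got <- globalAlign(s, t)
    expect_equal(got$score, oracleNWScore(s, t, B, 7, 1))
    # gap stripping recovers the inputs; identity bounded by shorter length
    expect_equal(gsub("-", "", got$aligned1), s)
    expect_equal(gsub("-", "", got$aligned2), t)
    expect_lte(got$n_identity, min(nchar(s), nchar(t)))
    expect_equal(nchar(got$aligned1), got$n_columns)
    expect_equal(nchar(got$aligned2), got$n_columns)
  }
})

test_that("alignment scores agree with an independent aligner", {
  library(Biostrings)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(13)
  for (i in 1:60) {
    s <- randomCDR3(1, 3, 18); t <- randomCDR3(1, 3, 18)
    mine <- globalAlign(s, t)$score
    # gap of length L costs 7 + (L-1) here and gapOpening + L*gapExtension
    # there, so gapOpening = 6 matches the -7/-1 regime
    ref <- pairwiseAlignment(s, t, substitutionMatrix = BLOSUM62,
                             gapOpening = 6, gapExtension = 1,
                             type = "global", scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("identity metrics divide exact matches by the right lengths", {
  aln <- globalAlign("CASS", "CASS")
  im <- identityMetrics(aln, 4, 4)
  expect_equal(im$value, c(1, 1, 1))

  aln <- globalAlign("CAS", "CASSL")
  im <- identityMetrics(aln, 3, 5)
  expect_equal(im$value[im$metric == "identity_short"], 1.0)
  expect_equal(im$value[im$metric == "identity_long"], 0.6)
  expect_equal(im$value[im$metric == "identity_alignment"], 0.6)

  set.seed(21)
  for (i in 1:25) {
    s <- randomCDR3(1, 3, 14); t <- randomCDR3(1, 3, 14)
    im <- identityMetrics(globalAlign(s, t), nchar(s), nchar(t))
    v <- setNames(im$value, im$metric)
    expect_gte(v[["identity_short"]], v[["identity_alignment"]] - 1e-12)
    expect_gte(v[["identity_short"]], v[["identity_long"]] - 1e-12)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("alignment-score metric is score over alignment length", {
  r <- computeMetric("alignment_score", "AAAA", "AAAA")
  expect_equal(r$value, 4)                       # blosum62(A,A) per column
  expect_lt(computeMetric("alignment_score", "AAAA", "AADA")$value, 4)
  aln <- globalAlign("CASRL", "CGSSL")
  expect_equal(alignmentScoreMetric(aln)$value, aln$score / aln$n_columns)
})

test_that("levenshtein distance matches a DP oracle and the metric axioms", {
  expect_equal(levenshteinDistance("CASSL", "CASSL")$value, 0)
  expect_equal(levenshteinDistance("CASSL", "CASSF")$value, 1)
  set.seed(17)
  for (i in 1:100) {
    s <- randomCDR3(1, 3, 12); t <- randomCDR3(1, 3, 12)
    expect_equal(levenshteinDistance(s, t)$value, oracleLevenshtein(s, t))
  }
  for (i in 1:40) {
    tri <- randomCDR3(3, 3, 10)
    d12 <- levenshteinDistance(tri[1], tri[2])$value
    d23 <- levenshteinDistance(tri[2], tri[3])$value
    d13 <- levenshteinDistance(tri[1], tri[3])$value
    expect_lte(d13, d12 + d23)
  }
})

test_that("tcrdist reproduces known values and an exhaustive oracle", {
  B <- blosum62LogOdds()
  set.seed(9)
  for (s in randomCDR3(10, 3, 12))
    expect_equal(tcrdistDistance(s, s)$value, 0)
  expect_equal(B["A", "G"], 0L)
  expect_equal(tcrdistDistance("A", "G")$value, 4)  # min(4, 4 - 0)
  for (i in 1:30) {
    s <- randomCDR3(1, 1, 4); t <- randomCDR3(1, 1, 4)
    expect_equal(tcrdistDistance(s, t)$value, oracleTCRdist(s, t, B))
  }
  # identical high-scoring residues still cost zero (W,W would go negative
  # under a naive capped formula)
  expect_equal(tcrdistDistance("WWW", "WWW")$value, 0)
})

test_that("computeMetric dispatches all seven metrics with orientations", {
  r <- computeMetric("tcrmatch", "CASSL", "CASSL")
  expect_equal(r$value, 1, tolerance = 1e-9)
  expect_equal(r$orientation, "similarity")
  r <- computeMetric("levenshtein", "CASSL", "CASSL")
  expect_equal(r$value, 0)
  expect_equal(r$orientation, "distance")
  expect_error(computeMetric("needleman", "A", "G"), "valid tokens")

  set.seed(23)
  for (i in 1:20) {
    s <- randomCDR3(1, 4, 14); t <- randomCDR3(1, 4, 14)
    for (m in metricTokens()) {
      v1 <- computeMetric(m, s, t)$value
      v2 <- computeMetric(m, t, s)$value
      expect_true(is.finite(v1))
      expect_equal(v1, v2, tolerance = 1e-9)   # symmetry
    }
  }
})

test_that("self-comparison attains each metric's extreme", {
  set.seed(31)
  seqs <- randomCDR3(15, 4, 14)
  for (m in metricTokens()) {
    self <- computeMetric(m, seqs[1], seqs[1])$value
    others <- vapply(seqs[-1], function(t)
      computeMetric(m, seqs[1], t)$value, 0)
    if (metricOrientationOf(m) == "similarity")
      expect_true(all(others <= self + 1e-9))
    else expect_true(all(others >= self - 1e-9))
  }
})

test_that("harsher gap penalties never add gap columns", {
  set.seed(37)
  soft <- alignmentParams(-7L, -1L)
  hard <- alignmentParams(-50L, -20L)
  countGaps <- function(aln)
    sum(strsplit(paste0(aln$aligned1, aln$aligned2), "")[[1]] == "-")
  for (i in 1:100) {
    s <- randomCDR3(1, 3, 15); t <- randomCDR3(1, 3, 15)
    expect_lte(countGaps(globalAlign(s, t, hard)),
               countGaps(globalAlign(s, t, soft)))
  }
})

test_that("alignment parameter validation enforces the penalty ordering", {
  expect_error(alignmentParams(-1L, -7L), "gap_open")
  expect_error(tcrdistParams(-1L), "non-negative")
  p <- alignmentParams(-50L, -20L)
  expect_equal(p$gap_open, -50L)
})
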