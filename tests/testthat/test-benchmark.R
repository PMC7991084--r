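# Evaluation engine: match calling, pooled precision/recall, ROC, sweeps,
# partial AUC, paired-chain averaging.

test_that("worked toy example: three matches, precision 2/5, recall 1/3", {
  S <- matrix(c(0.99, 0.93, 0.17, 0.91), nrow = 1)
  qeps <- list(c("E1", "E2", "E3"))
  reps <- list(c("E1", "E4"), "E5", "E7", c("E1", "E4"))
  p <- precisionRecallFromScores(S, qeps, reps, threshold = 0.9,
                                 orientation = "similarity")
  expect_equal(p$tp, 2)
  expect_equal(p$fp, 3)
  expect_equal(p$precision, 2 / 5)
  expect_equal(p$recall, 1 / 3)
})

test_that("match calling excludes self and respects the inclusive cutoff", {
  db <- referenceDatabase(cdr3b = c("ASSLGQE", "ASSLGQD", "ARDTQYE"),
                          epitopes = list("E1", "E1", "E2"),
                          antigen = c("a1", "a1", "a2"))
  q <- receptorGroup("ASSLGQE", "E1", group_id = "G1")
  m <- callMatches(q, db, threshold = 1.0)
  expect_false("G1" %in% m$group_id)           # self excluded by identity
  expect_equal(nrow(m), 2L)
  expect_false(any(m$matched))                 # no other exact duplicate

  # an exact duplicate under a different group id matches at threshold 1
  db2 <- referenceDatabase(cdr3b = c("ASSLGQE", "ARDTQYE"),
                           epitopes = list(c("E1", "E9"), "E2"))
  q2 <- receptorGroup("ASSLGQE", "E1", group_id = "Q1")
  m2 <- callMatches(q2, db2, threshold = 1.0)
  hit <- m2[m2$matched, ]
  expect_equal(hit$group_id, "G1")
  expect_equal(hit$score, 1, tolerance = 1e-9)
  expect_equal(hit$shared, "E1")
  expect_equal(hit$unshared, "E9")

  # a threshold above every score matches nothing
  m3 <- callMatches(q, db, threshold = 1.1)
  expect_false(any(m3$matched))
})

test_that("pooled precision/recall equals an explicit enumeration", {
  for (s in 1:3) {
    db <- generateSynthetic(n_groups = 10, n_epitopes = 3,
                            singleton_fraction = 0, seed = 40 + s)
    q <- TCRMatchR:::.asGroups(db)
    for (metric in c("tcrmatch", "levenshtein")) {
      S <- TCRMatchR:::.metricMatrix(metric, q$seqs, q$seqs)
      orient <- metricOrientationOf(metric)
      excl <- diag(nrow(S)) > 0
      thr <- if (metric == "tcrmatch") c(0.6, 0.9) else c(2, 5)
      for (t in thr) {
        got <- precisionRecall(db, db, metric, threshold = t)
        ref <- oraclePR(S, q$epitopes, q$epitopes, t, orient, excl)
        expect_equal(got$tp, ref$tp)
        expect_equal(got$fp, ref$fp)
        expect_equal(got$precision, ref$precision)
        expect_equal(got$recall, ref$recall)
        expect_equal(got$tpr, ref$tpr)
        expect_equal(got$fpr, ref$fpr)
        # the score-matrix entry point agrees with the database entry point
        alt <- precisionRecallFromScores(S, q$epitopes, q$epitopes, t,
                                         orient, exclude = excl)
        expect_equal(alt$tp, got$tp)
        expect_equal(alt$recall, got$recall)
      }
    }
  }
})

test_that("ROC endpoints behave and match enumeration", {
  db <- generateSynthetic(n_groups = 12, n_epitopes = 3,
                          singleton_fraction = 0, seed = 77)
  r <- rocPoint(db, db, "tcrmatch", threshold = 0)      # everything matches
  expect_equal(unname(r), c(1, 1))
  r <- rocPoint(db, db, "tcrmatch", threshold = 1.0001)
  expect_equal(unname(r), c(0, 0))
  q <- TCRMatchR:::.asGroups(db)
  S <- TCRMatchR:::.metricMatrix("tcrmatch", q$seqs, q$seqs)
  ref <- oraclePR(S, q$epitopes, q$epitopes, 0.8, "similarity",
                  diag(nrow(S)) > 0)
  r <- rocPoint(db, db, "tcrmatch", threshold = 0.8)
  expect_equal(unname(r), c(ref$tpr, ref$fpr))
})

test_that("threshold sweeps are monotone, deterministic, and carry presets", {
  db <- generateSynthetic(n_groups = 60, n_epitopes = 10, seed = 8)
  cs <- sweepThresholds(db, db, "tcrmatch", n_points = 41L)
  p <- curvePoints(cs)
  expect_true(all(c(0.84, 0.90, 0.97) %in% p$threshold))
  expect_true(all(diff(p$recall) <= 1e-12))   # stricter cutoff, lower recall
  expect_true(all(diff(p$tp) <= 0))
  cs2 <- sweepThresholds(db, db, "tcrmatch", n_points = 41L)
  expect_identical(curvePoints(cs2), p)

  # distance metrics: recall grows with the (ascending) distance cutoff
  cd <- curvePoints(sweepThresholds(db, db, "levenshtein", n_points = 41L))
  expect_true(all(diff(cd$recall) >= -1e-12))
  expect_error(sweepThresholds(db, db, "tcrmatch", thresholds = c(1, 0.5)),
               "sorted")
})

test_that("partial AUC handles rectangles, windows, and edges", {
  flat <- data.frame(recall = seq(0, 1, 0.1), precision = 1)
  expect_equal(partialAUC(flat), 0.5)
  flat$precision <- 0.37
  expect_equal(partialAUC(flat), 0.5 * 0.37)
  # triangle: precision = recall over [0, 0.5] integrates to 0.125
  tri <- data.frame(recall = seq(0, 1, 0.05), precision = seq(0, 1, 0.05))
  expect_equal(partialAUC(tri), 0.125)
  # window-edge interpolation against a dense numerical integral
  f <- function(r) 0.9 - 0.6 * r + 0.2 * r^2
  coarse <- data.frame(recall = seq(0.03, 0.97, length.out = 15),
                       precision = f(seq(0.03, 0.97, length.out = 15)))
  dense <- data.frame(recall = seq(0.03, 0.97, length.out = 4001),
                      precision = f(seq(0.03, 0.97, length.out = 4001)))
  expect_equal(partialAUC(coarse, 0.1, 0.5), partialAUC(dense, 0.1, 0.5),
               tolerance = 2e-3)
  # curve never reaches the window floor: absent
  expect_true(is.na(partialAUC(data.frame(recall = 0.2, precision = 0.5),
                               0.4, 0.5)))
  expect_true(is.na(partialAUC(data.frame(recall = numeric(),
                                          precision = numeric()))))
  # support above the floor only: first precision extends down as a constant
  step <- data.frame(recall = c(0.4, 0.6), precision = c(0.8, 0.5))
  expect_equal(partialAUC(step, 0, 0.5),
               0.4 * 0.8 + 0.1 * (0.8 + 0.65) / 2)
  # the strictest tied block spans the whole window: constant precision
  expect_equal(partialAUC(data.frame(recall = 0.9, precision = 0.5), 0, 0.5),
               0.25)
  expect_error(partialAUC(flat, 0.5, 0.5), "recall_lo")
})

test_that("uniform-epitope null gives chance precision of about 1/E", {
  set.seed(55)
  E <- 8; n <- 160
  seqs <- unique(randomCDR3(2 * n, 8, 14))[seq_len(n)]
  db <- referenceDatabase(seqs, as.list(rep(paste0("E", 1:E), length.out = n)))
  p <- precisionRecall(db, db, "tcrmatch", threshold = 0)
  # exact combinatorial value: each query has n/E - 1 co-specific partners
  expect_equal(p$precision, (n / E - 1) / (n - 1), tolerance = 1e-12)
  expect_equal(p$precision, 1 / E, tolerance = 0.05)
})

test_that("paired scoring averages the two chains and stays symmetric", {
  a1 <- "AVRGDSNYQL"; b1 <- "ASSLGQETQY"
  a2 <- "AVRGDTNYQL"; b2 <- "ASSPGQETQY"
  got <- pairedScore("tcrmatch", a1, b1, a2, b2)
  expect_equal(got$value,
               (computeMetric("tcrmatch", a1, a2)$value +
                  computeMetric("tcrmatch", b1, b2)$value) / 2)
  expect_equal(got$value, pairedScore("tcrmatch", a2, b2, a1, b1)$value)
  expect_equal(pairedScore("tcrmatch", a1, b1, a1, b1)$value, 1,
               tolerance = 1e-9)
  expect_equal(pairedScore("levenshtein", a1, b1, a1, b1)$value, 0)
  # alpha/beta chains and paired averaging through the sweep interface
  db <- generateSynthetic(n_groups = 30, n_epitopes = 6, seed = 21,
                          with_alpha = TRUE)
  pb <- precisionRecall(db, db, "tcrmatch", 0.9, chain = "beta")
  pp <- precisionRecall(db, db, "tcrmatch", 0.9, chain = "paired")
  expect_true(is.finite(pp$precision) || is.na(pp$precision))
  expect_false(identical(pb, pp))
})
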