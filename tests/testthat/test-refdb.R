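# Reference-database model: merging, I/O, assembly filters, shuffle control.

smallDB <- function() {
  referenceDatabase(
    cdr3b = c("ASSLG", "ASSQE", "ASRDT", "ASSYE"),
    epitopes = list(c("E1", "E2"), "E1", "E3", "E3"),
    antigen = c("ag1", "ag1", "ag2", "ag2"),
    organism = "test")
}

test_that("identical CDR3beta records merge with the union of epitopes", {
  db <- referenceDatabase(cdr3b = c("ASSLG", "ASSLG", "ASRDT"),
                          epitopes = list("E1", "E2", "E1"))
  expect_equal(nGroups(db), 2L)
  g <- which(cdr3b(db) == "ASSLG")
  expect_setequal(epitopeList(db)[[g]], c("E1", "E2"))
  idx <- epitopeIndex(db)
  expect_equal(sort(names(idx)), c("E1", "E2"))
  expect_equal(length(idx$E1), 2L)
})

test_that("validity catches malformed databases", {
  db <- smallDB()
  bad <- db
  bad@groups$group_id[2] <- bad@groups$group_id[1]
  expect_error(validObject(bad), "unique")
  bad <- db
  bad@epitopes[[1]] <- character()
  expect_error(validObject(bad), "epitope")
})

test_that("reference TSV round-trips losslessly", {
  db <- generateSynthetic(n_groups = 40, n_epitopes = 8, seed = 3,
                          with_alpha = TRUE)
  path <- tempfile(fileext = ".tsv")
  writeReferenceTSV(db, path)
  back <- readReferenceTSV(path)
  expect_equal(back@groups$cdr3b, db@groups$cdr3b)
  expect_equal(back@groups$cdr3a, db@groups$cdr3a)
  expect_equal(unname(lapply(epitopeList(back), sort)),
               unname(lapply(epitopeList(db), sort)))
  expect_equal(back@groups$antigen, db@groups$antigen)
})

test_that("reader trims flanks, skips bad rows, and logs provenance", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("group_id\tcdr3b\tcdr3a\tepitopes\tantigen\torganism",
               "G1\tCASSLGF\t\tE1,E2\tag\torg",     # trims to ASSLG
               "G2\t\t\tE1\tag\torg",               # no cdr3b: skipped
               "G3\tASSQE\t\t\tag\torg",            # no epitope: skipped
               "G4\tASSQE\t\tE1\tag\torg",
               "G5\tCF\t\tE9\tag\torg"),            # trims too short: skipped
             path)
  expect_warning(db <- readReferenceTSV(path), "unusable")
  expect_equal(nGroups(db), 2L)
  expect_setequal(unname(cdr3b(db)), c("ASSLG", "ASSQE"))
  expect_match(provenance(db)$detail[1], "5 rows read, 2 lacking")
  expect_error(readReferenceTSV(tempfile()), "not found")

  # missing mandatory column is a format error
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("cdr3b\tantigen", "ASSLG\tag"), path2)
  expect_error(readReferenceTSV(path2), "epitopes")

  # empty body gives an empty database
  path3 <- tempfile(fileext = ".tsv")
  writeLines("group_id\tcdr3b\tcdr3a\tepitopes\tantigen\torganism", path3)
  db3 <- readReferenceTSV(path3)
  expect_equal(nGroups(db3), 0L)
})

test_that("singleton filtering removes exactly the unsupported epitopes", {
  db <- smallDB()   # E2 is a singleton; E1 and E3 both have two groups
  f <- filterSingletonEpitopes(db)
  expect_equal(sort(names(epitopeIndex(f))), c("E1", "E3"))
  expect_equal(nGroups(f), 4L)      # ASSLG keeps E1

  # a group whose only epitope is a singleton disappears with it
  db2 <- referenceDatabase(cdr3b = c("ASSLG", "ASSQE", "ASRDT"),
                           epitopes = list("E1", "E1", "E9"))
  f2 <- filterSingletonEpitopes(db2)
  expect_equal(nGroups(f2), 2L)
  expect_equal(names(epitopeIndex(f2)), "E1")

  # no singletons: unchanged groups and epitopes
  f3 <- filterSingletonEpitopes(f2)
  expect_equal(nGroups(f3), nGroups(f2))

  # fixpoint property on generated databases: every epitope supported twice
  for (s in 1:5) {
    db <- generateSynthetic(n_groups = 60, n_epitopes = 12, seed = s)
    f <- filterSingletonEpitopes(db)
    expect_true(all(lengths(epitopeIndex(f)) >= 2L))
  }
})

test_that("shuffle control conserves both multisets and is deterministic", {
  db <- generateSynthetic(n_groups = 120, n_epitopes = 20, seed = 4)
  sh <- shuffleControl(db, seed = 99)
  expect_equal(sort(unname(unlist(epitopeList(sh)))),
               sort(unname(unlist(epitopeList(db)))))
  expect_equal(lengths(epitopeList(sh)), lengths(epitopeList(db)))
  expect_equal(cdr3b(sh), cdr3b(db))
  # no within-group duplicate epitopes after the repair step
  expect_true(all(vapply(epitopeList(sh), anyDuplicated, 0L) == 0L))
  sh2 <- shuffleControl(db, seed = 99)
  expect_identical(sh@epitopes, sh2@epitopes)
  sh3 <- shuffleControl(db, seed = 100)
  expect_false(identical(sh@epitopes, sh3@epitopes))
})

test_that("paired assembly keeps unique two-chain receptors only", {
  db <- referenceDatabase(
    cdr3b = c("ASSLG", "ASSQE", "ASRDT", "ASSYE", "ASSPD"),
    epitopes = list("E1", "E1", "E2", "E2", "E2"),
    cdr3a = c("AVRG", "AVRG", "ALSD", NA, "AGNT"),
    merge = FALSE)
  out <- assemblePaired(db)
  # ASSYE lacks an alpha chain; ASSLG and ASSQE share one alpha: all removed
  expect_equal(sort(unname(cdr3b(out))), c("ASRDT", "ASSPD"))
  expect_false(anyDuplicated(out@groups$cdr3a) > 0)
  expect_false(anyDuplicated(out@groups$cdr3b) > 0)
  expect_true(all(lengths(epitopeIndex(out)) >= 2L))
  steps <- provenance(out)$step
  expect_true(all(c("paired_both_chains", "paired_unique_chains",
                    "filter_singleton_epitopes") %in% steps))
})

test_that("query readers handle plain text and AIRR rearrangement TSV", {
  p <- tempfile()
  writeLines(c("CASSLGF", "", " ASSQE "), p)
  expect_equal(readQueries(p), c("CASSLGF", "ASSQE"))

  airr <- tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tjunction_aa\tv_call",
               "s1\tCASSLGF\tTRBV1", "s2\tCASSQETQYF\tTRBV2"), airr)
  expect_equal(readQueries(airr, format = "airr"),
               c("CASSLGF", "CASSQETQYF"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tjunction", "s1\tCASSLGF"), bad)
  expect_error(readQueries(bad, format = "airr"), "junction_aa")
})
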