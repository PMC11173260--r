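test_that("FASTA reading parses headers, folds case and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "acde", ">P2", "ACDF"), f)
  es <- readFastaSet(f)
  expect_s4_class(es, "EnzymeSet")
  expect_equal(seqIds(es), c("P1", "P2"))
  expect_equal(as.character(sequences(es))[["P1"]], "ACDE")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "ACDE", ">P1", "ACDF"), dup)
  expect_error(readFastaSet(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(readFastaSet(empty), "empty")
})

test_that("FASTA write/read round-trips a validated dataset", {
  set.seed(7)
  es <- EnzymeSet(stats::setNames(vapply(1:5, function(i) randomSeq(30), ""),
                                  paste0("S", 1:5)))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSet(es, f)
  back <- readFastaSet(f)
  expect_equal(seqIds(back), seqIds(es))
  expect_equal(as.character(sequences(back)), as.character(sequences(es)))
})

test_that("dataset tables are parsed with typing and row errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ec,topt,seq",
               "P1,3.1.3.8,55,ACDE",
               "P2,3.1.3.26,47.5,ACDF",
               "P3,3.1.3.8,,ACDG"), f)
  es <- readDatasetTable(f)
  expect_equal(length(es), 3L)
  expect_equal(seqIds(es), c("P1", "P2", "P3"))  # order preserved
  expect_equal(unname(ecNumbers(es)[1]), "3.1.3.8")
  expect_equal(unname(toptValues(es)), c(55, 47.5, NA))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ec,topt,seq", "P1,3.1.3.8,abc,ACDE"), bad)
  expect_error(readDatasetTable(bad), "topt at data row 1")

  noCol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,topt,seq", "P1,55,ACDE"), noCol)
  expect_error(readDatasetTable(noCol), "ec")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDatasetTable(es, tsv)
  expect_equal(unname(toptValues(readDatasetTable(tsv))), c(55, 47.5, NA))
})

test_that("residue validation accepts the canonical alphabet and names offenders", {
  expect_identical(validateResidues("ACDEFGHIKLMNPQRSTVWY"),
                   "ACDEFGHIKLMNPQRSTVWY")
  expect_error(validateResidues("ACXDE"), "'X' at position 2")
  expect_error(validateResidues(""), "empty")
  expect_error(EnzymeSet(c(a = "ACBDE")), "non-canonical")
  expect_error(EnzymeSet(c(a = "ACDE"), topt = 150), "Topt")
})

test_that("EC grouping is a lexicographically ordered partition", {
  es <- EnzymeSet(c(a = "ACDE", b = "ACDF", c = "ACDG"),
                  ec = c("3.1.3.8", "3.1.3.8", "3.1.3.26"))
  g <- groupByEC(es)
  expect_equal(names(g), c("3.1.3.26", "3.1.3.8"))
  expect_equal(vapply(g, length, 0L), c("3.1.3.26" = 1L, "3.1.3.8" = 2L))
  # partition: sizes sum, no id in two groups
  ids <- unname(unlist(lapply(g, seqIds)))
  expect_equal(sort(ids), sort(seqIds(es)))
  expect_false(anyDuplicated(ids) > 0)

  expect_equal(length(groupByEC(EnzymeSet(character(0)))), 0L)
  noEc <- EnzymeSet(c(a = "ACDE"), ec = NA)
  expect_error(groupByEC(noEc), "a")
})

test_that("baseline filters drop short sequences then singleton groups, idempotently", {
  set.seed(1)
  g <- list(
    "3.1.3.1" = EnzymeSet(c(a = randomSeq(40), b = randomSeq(60),
                            c = randomSeq(60)),
                          ec = rep("3.1.3.1", 3)),
    "3.1.3.2" = EnzymeSet(c(d = randomSeq(40), e = randomSeq(60)),
                          ec = rep("3.1.3.2", 2)),
    "3.1.3.3" = EnzymeSet(c(f = randomSeq(55), h = randomSeq(70)),
                          ec = rep("3.1.3.3", 2)))
  res <- applyBaselineFilters(g, minLen = 50)
  expect_equal(names(res$groups), c("3.1.3.1", "3.1.3.3"))
  expect_equal(length(res$groups[["3.1.3.1"]]), 2L)
  expect_equal(res$log$reason[res$log$id == "a"], "short-sequence")
  # group 3.1.3.2 lost 'd' to the length filter, then 'e' as a singleton
  expect_setequal(res$log$id[res$log$group == "3.1.3.2"], c("d", "e"))
  expect_true("singleton-group" %in%
                res$log$reason[res$log$group == "3.1.3.2"])
  # idempotence
  res2 <- applyBaselineFilters(res$groups, minLen = 50)
  expect_equal(names(res2$groups), names(res$groups))
  expect_equal(nrow(res2$log), 0L)
  # identity case
  res3 <- applyBaselineFilters(g["3.1.3.3"], minLen = 50)
  expect_equal(vapply(res3$groups, seqIds, character(2)),
               vapply(g["3.1.3.3"], seqIds, character(2)))
})

test_that("EnzymeSet subsetting and combination preserve annotation", {
  es <- EnzymeSet(c(a = "ACDE", b = "ACDF", c = "ACDG"),
                  ec = c("3.1.3.8", "3.1.3.8", "3.1.3.26"),
                  topt = c(50, 60, 70))
  sub <- es[c("c", "a")]
  expect_equal(unname(toptValues(sub)), c(70, 50))
  expect_error(es["zz"], "unknown record id")
  comb <- combineSets(list(sub, es["b"]))
  expect_equal(length(comb), 3L)
  expect_equal(unname(ecNumbers(comb)["b"]), "3.1.3.8")
})
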