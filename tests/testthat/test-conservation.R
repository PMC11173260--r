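test_that("pairwise global alignment matches a brute-force DP oracle", {
  # fixed example: one gap in the shorter sequence, score 3 - 1 = 2
  al <- pairwiseGlobalAlign("ACDE", "ADE", match = 1, mismatch = 0,
                            gapOpening = 0, gapExtension = 1)
  expect_equal(al$score, 2)
  expect_equal(nchar(al$alignedA), nchar(al$alignedB))
  expect_equal(oracleAlignScore("ACDE", "ADE"), 2)

  # random sequences, linear gap costs so oracle and aligner agree exactly
  set.seed(11)
  for (i in 1:25) {
    a <- randomSeq(sample(3:12, 1))
    b <- randomSeq(sample(3:12, 1))
    al <- pairwiseGlobalAlign(a, b, match = 2, mismatch = -1,
                              gapOpening = 0, gapExtension = 2)
    expect_equal(al$score, oracleAlignScore(a, b, 2, -1, -2))
  }
})

test_that("self-alignment has no gaps and the diagonal substitution score", {
  al <- pairwiseGlobalAlign("ACDE", "ACDE")
  expect_equal(al$alignedA, "ACDE")
  expect_equal(al$alignedB, "ACDE")
  b62 <- as.matrix(read.table(text =
    "A C D E\nA 4 0 -2 -1\nC 0 9 -3 -4\nD -2 -3 6 2\nE -1 -4 2 5",
    header = TRUE, check.names = FALSE))
  expect_equal(al$score, sum(diag(b62)))  # 4 + 9 + 6 + 5

  one <- pairwiseGlobalAlign("A", "C")
  expect_equal(one$alignedA, "A")
  expect_equal(one$score, 0)  # BLOSUM62 A-vs-C substitution
  expect_error(pairwiseGlobalAlign("", "A"), "empty")
})

test_that("progressive MSA round-trips inputs through gap removal", {
  # identical sequences align without gaps
  msa <- progressiveMSA(EnzymeSet(c(a = "ACDEF", b = "ACDEF")))
  expect_equal(unname(msaRows(msa)), c("ACDEF", "ACDEF"))

  # a deletion yields one gap in the shorter row
  msa2 <- progressiveMSA(EnzymeSet(c(a = "ACDE", b = "ACE")))
  expect_equal(msaWidth(msa2), 4L)
  expect_equal(sum(strsplit(msaRows(msa2)[["b"]], "")[[1]] == "-"), 1L)

  expect_error(progressiveMSA(EnzymeSet(c(a = "ACDE"))), "singleton")

  # random gapped families: indels in variable regions
  set.seed(5)
  for (rep in 1:5) {
    base <- randomSeq(40)
    seqs <- vapply(1:4, function(i) {
      s <- strsplit(base, "")[[1]]
      cut <- sample(40, sample(0:4, 1))
      if (length(cut)) s <- s[-cut]
      paste(s, collapse = "")
    }, "")
    names(seqs) <- paste0("m", 1:4)
    es <- EnzymeSet(seqs)
    msa <- progressiveMSA(es)
    expect_equal(degapRows(msa), seqs)
    expect_equal(length(unique(nchar(msaRows(msa)))), 1L)
  }
})

test_that("conserved columns require a shared non-gap residue", {
  m <- findConservedColumns(asProteinMSA(c(a = "ACD", b = "ACE")))
  expect_equal(conservedColumns(m), c(0L, 1L))
  expect_equal(unname(conservedResidues(m)), c("A", "C"))

  # a gap disqualifies a column at threshold 1
  g <- findConservedColumns(asProteinMSA(c(a = "A-D", b = "ACD")))
  expect_equal(conservedColumns(g), c(0L, 2L))

  all3 <- findConservedColumns(asProteinMSA(c(a = "ACD", b = "ACD",
                                              c = "ACD")))
  expect_equal(conservedColumns(all3), 0:2)
  expect_equal(unname(conservedPositions(all3)[["b"]]), 0:2)
})

test_that("conservation detection is row-order invariant and threshold monotone", {
  set.seed(19)
  fam <- generateFamily(familyParams(nMembers = 6, scaffoldLength = 20,
                                     variableLength = 12, seed = 19),
                        forceVariableDiff = TRUE)
  msa <- progressiveMSA(fam$set)
  m1 <- findConservedColumns(msa)
  perm <- sample(seqIds(msa))
  m2 <- findConservedColumns(asProteinMSA(msaRows(msa)[perm]))
  expect_equal(conservedColumns(m1), conservedColumns(m2))

  # lowering the threshold never removes a conserved column
  for (th in c(0.9, 0.7, 0.5)) {
    mt <- findConservedColumns(msa, threshold = th)
    expect_true(all(conservedColumns(m1) %in% conservedColumns(mt)))
  }

  # mapped positions carry the conserved residue in the original sequence
  seqs <- degapRows(msa)
  res <- conservedResidues(m1)
  for (id in names(seqs)) {
    pos <- conservedPositions(m1)[[id]]
    expect_equal(strsplit(seqs[[id]], "")[[1]][pos + 1L], unname(res))
  }
})

test_that("stripConserved removes exactly the listed positions", {
  expect_equal(stripConserved("ACDE", c(0, 1)), "DE")
  expect_equal(stripConserved("ACDE", integer(0)), "ACDE")
  expect_equal(stripConserved("ACDE", 0:3), "")
  expect_error(stripConserved("ACDE", 4), "position")
})

test_that("stripGroup pairs datasets, enforces the length floor and flags low conservation", {
  fam <- generateFamily(familyParams(nMembers = 4, scaffoldLength = 30,
                                     variableLength = 60, seed = 23),
                        forceVariableDiff = TRUE)
  res <- stripGroup(fam$set, minRcaaLen = 50)
  nCons <- length(conservedColumns(res$map))
  expect_equal(nCons, 30L)
  # arithmetic invariant: original length = stripped + conserved count
  expect_equal(nchar(as.character(sequences(res$original))),
               nchar(as.character(sequences(res$rcaa))) + nCons,
               ignore_attr = TRUE)
  expect_equal(seqIds(res$rcaa), seqIds(res$original))
  expect_false(res$lowConservation)

  # stripped below the floor: dropped from BOTH outputs and logged
  res2 <- stripGroup(fam$set, minRcaaLen = 70)
  expect_equal(length(res2$rcaa), 0L)
  expect_equal(length(res2$original), 0L)
  expect_equal(nrow(res2$log), 4L)

  # a family with no conserved columns: rcaa = originals, flag raised
  set.seed(4)
  div <- EnzymeSet(stats::setNames(vapply(1:3, function(i) randomSeq(60), ""),
                                   paste0("d", 1:3)))
  aln <- asProteinMSA(stats::setNames(as.character(sequences(div)),
                                      seqIds(div)))
  if (length(conservedColumns(findConservedColumns(aln))) == 0) {
    res3 <- stripGroup(div, alignment = aln, minRcaaLen = 50)
    expect_true(res3$lowConservation)
    expect_equal(as.character(sequences(res3$rcaa)),
                 as.character(sequences(div)), ignore_attr = TRUE)
  }
  expect_error(stripGroup(EnzymeSet(c(a = "ACDE"))), "singleton")
})

test_that("a pre-computed aligned FASTA yields the same conservation map", {
  fam <- generateFamily(familyParams(nMembers = 5, scaffoldLength = 25,
                                     variableLength = 15, seed = 31),
                        forceVariableDiff = TRUE)
  msa <- progressiveMSA(fam$set)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSet(msa, f)
  back <- readAlignedFasta(f)
  m1 <- findConservedColumns(msa)
  m2 <- findConservedColumns(back)
  expect_equal(conservedColumns(m1), conservedColumns(m2))
  expect_equal(conservedPositions(m1), conservedPositions(m2))
  # and stripGroup accepts the external alignment in place of its own
  res <- stripGroup(fam$set, alignment = back, minRcaaLen = 10)
  expect_equal(length(conservedColumns(res$map)), 25L)
})
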