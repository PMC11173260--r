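test_that("amino acid frequencies are normalised counts in canonical order", {
  expect_equal(unname(aaFrequency("AAAA")["A"]), 1)
  expect_equal(sum(aaFrequency("AAAA")), 1)
  expect_equal(unname(aaFrequency("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  f <- aaFrequency("GGGC")
  expect_equal(unname(f["G"]), 0.75)
  expect_equal(unname(f["C"]), 0.25)
  expect_equal(names(f), AA_CANONICAL)
  expect_error(aaFrequency(""), "empty")
})

test_that("dipeptide frequencies match brute-force window counts", {
  expect_equal(unname(dipeptideFrequency("AA")["AA"]), 1)
  f <- dipeptideFrequency("ACAC")
  expect_equal(unname(f["AC"]), 2 / 3)
  expect_equal(unname(f["CA"]), 1 / 3)
  f2 <- dipeptideFrequency("ACDEF")
  expect_equal(sort(unname(f2[f2 > 0])), rep(0.25, 4))
  expect_error(dipeptideFrequency("A"), "length >= 2")

  set.seed(8)
  for (i in 1:20) {
    s <- randomSeq(sample(2:30, 1))
    f <- dipeptideFrequency(s)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    counts <- oracleDipeptideCounts(s)
    expect_equal(unname(f[names(counts)]),
                 as.numeric(counts) / (nchar(s) - 1))
  }
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecularWeight("GG"), 132.12, tolerance = 0.01)
  # peptide-bond additivity
  set.seed(2)
  s1 <- randomSeq(12); s2 <- randomSeq(9)
  expect_equal(molecularWeight(paste0(s1, s2)),
               molecularWeight(s1) + molecularWeight(s2) - 18.0153,
               tolerance = 1e-6)
})

test_that("molecular weight agrees with an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(21)
  for (i in 1:10) {
    s <- randomSeq(sample(5:80, 1))
    expect_equal(molecularWeight(s),
                 seqinr::pmw(strsplit(s, "")[[1]]),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})

test_that("conjoint triads count class triples over sliding windows", {
  v <- conjointTriad("AAA")
  expect_length(v, 343L)
  expect_equal(unname(v["CT.1.1.1"]), 1)   # (count - min)/max = (1-0)/1
  expect_equal(sum(v), 1)
  # A, G, V share class 1: same triple as AAA
  expect_equal(conjointTriad("AGV"), conjointTriad("AAA"))
  raw <- conjointTriad("AAAA", raw = TRUE)
  expect_equal(unname(raw["CT.1.1.1"]), 2)
  expect_error(conjointTriad("AA"), "length >= 3")
})

test_that("distribution descriptors report quantile positions per attribute group", {
  v <- ctdd("AAAA")
  expect_length(v, 105L)
  expect_true(all(v >= 0 & v <= 100))
  # A is hydrophobicity group 2: first/25/50/75/100% at 25,25,50,75,100
  expect_equal(unname(v[grep("hydrophobicity.G2", names(v))]),
               c(25, 25, 50, 75, 100))
  # groups with no member are all zero
  expect_equal(unname(v[grep("hydrophobicity.G1", names(v))]), rep(0, 5))
  set.seed(6)
  for (i in 1:10) {
    vv <- ctdd(randomSeq(sample(1:40, 1)))
    expect_true(all(vv >= 0 & vv <= 100))
  }
})

test_that("the 12 descriptor combinations have their published dimensions", {
  expect_equal(comboDimensions(),
               c(20L, 400L, 420L, 468L, 848L, 868L,
                 21L, 401L, 421L, 469L, 849L, 869L))
  set.seed(9)
  es <- EnzymeSet(stats::setNames(vapply(1:3, function(i) randomSeq(25), ""),
                                  paste0("p", 1:3)))
  for (combo in c(1L, 4L, 7L, 12L)) {
    fm <- buildFeatureMatrix(es, combo)
    expect_equal(ncol(featureValues(fm)), comboDimensions()[combo])
    expect_equal(rownames(featureValues(fm)), seqIds(es))
  }
  # combo 1 is exactly the amino-acid frequency block
  fm1 <- buildFeatureMatrix(es, 1)
  expect_equal(featureValues(fm1)["p1", ],
               aaFrequency(as.character(sequences(es))[1]))
  expect_error(buildFeatureMatrix(es, 13), "comboId")
  short <- EnzymeSet(c(tiny = "AC"))
  expect_error(buildFeatureMatrix(short, 4), "tiny.*CTF")
})

test_that("standardization fits on the training matrix only", {
  set.seed(14)
  tr <- EnzymeSet(stats::setNames(vapply(1:8, function(i) randomSeq(30), ""),
                                  paste0("t", 1:8)))
  te <- EnzymeSet(stats::setNames(vapply(1:3, function(i) randomSeq(30), ""),
                                  paste0("q", 1:3)))
  fmTr <- buildFeatureMatrix(tr, 7)
  fmTe <- buildFeatureMatrix(te, 7)
  z <- standardizeFeatures(fmTr, list(fmTe))
  vTr <- featureValues(z$train)
  keep <- apply(featureValues(fmTr), 2, sd) > 0
  expect_equal(unname(colMeans(vTr)[keep]), rep(0, sum(keep)),
               tolerance = 1e-9)
  expect_equal(unname(apply(vTr[, keep], 2, sd)), rep(1, sum(keep)),
               tolerance = 1e-9)
  # constant columns become zeros
  expect_equal(unname(vTr[, !keep]), matrix(0, nrow(vTr), sum(!keep)),
               ignore_attr = TRUE)
  # the test matrix is scaled with TRAINING statistics
  expect_equal(featureValues(z$others[[1]]),
               sweep(sweep(featureValues(fmTe), 2, z$scaler$center, "-"),
                     2, z$scaler$scale, "/"))
  # standardizing twice is refused
  expect_error(standardizeFeatures(z$train), "already standardized")
})
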