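# deterministic labeled set whose Topt is an exact linear function of
# sequence composition (fraction of R among 30 residues)
linearFixture <- function(n = 60L, len = 30L) {
  f <- seq(0.05, 0.95, length.out = n)
  nR <- round(len * f)
  seqs <- vapply(nR, function(k)
    paste(c(rep("R", k), rep("A", len - k)), collapse = ""), "")
  names(seqs) <- sprintf("L%03d", seq_len(n))
  EnzymeSet(seqs, ec = rep("3.1.3.1", n), topt = 15 + 80 * nR / len)
}

test_that("stratified splitting draws a quarter of the smallest bin from every bin", {
  set.seed(33)
  y <- c(runif(8, 1, 29), runif(110, 30, 49), runif(60, 50, 64),
         runif(32, 65, 84), runif(8, 85, 99))
  idx <- stratifiedSplitIndices(y, splitPlan(seed = 5))
  expect_equal(idx$perBin, 2L)
  expect_equal(length(idx$testIdx), 10L)
  bins <- findInterval(y[idx$testIdx], c(0, 30, 50, 65, 85, 100),
                       rightmost.closed = TRUE)
  expect_equal(unname(table(bins)), rep(2L, 5), ignore_attr = TRUE)
  # disjoint and covering
  expect_equal(sort(c(idx$trainIdx, idx$testIdx)), seq_along(y))
  # determinism
  idx2 <- stratifiedSplitIndices(y, splitPlan(seed = 5))
  expect_identical(idx$testIdx, idx2$testIdx)

  y2 <- c(runif(4, 1, 29), runif(4, 30, 49), runif(4, 50, 64),
          runif(4, 65, 84), runif(4, 85, 99))
  expect_equal(length(stratifiedSplitIndices(y2, splitPlan())$testIdx), 5L)
  expect_error(stratifiedSplitIndices(c(10, 40), splitPlan()), "empty")
})

test_that("stratifiedSplit partitions an EnzymeSet by record", {
  es <- linearFixture()
  sp <- stratifiedSplit(es, splitPlan(seed = 2))
  expect_setequal(c(seqIds(sp$train), seqIds(sp$test)), seqIds(es))
  expect_length(intersect(seqIds(sp$train), seqIds(sp$test)), 0)
})

test_that("the regressor registry fits and predicts deterministically", {
  set.seed(41)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- 2 * X[, 1] + 30

  # OLS recovers an exact linear relationship
  ols <- fitRegressor(modelSpec("ols"), X, y)
  expect_equal(unname(ols$coef["(Intercept)"]), 30, tolerance = 1e-8)
  expect_equal(unname(ols$coef[2]), 2, tolerance = 1e-8)
  expect_equal(predictRegressor(ols, X), y, tolerance = 1e-8)

  # 1-NN retrieves training labels exactly
  knn1 <- fitRegressor(modelSpec("knn", k = 1), X, y)
  expect_equal(predictRegressor(knn1, X), y)
  # uniform-weight KNN is the mean of the K nearest labels
  knn3 <- fitRegressor(modelSpec("knn", k = 3), X, y)
  d <- as.matrix(dist(rbind(X[1, ], X)))[1, -1]
  expect_equal(predictRegressor(knn3, X[1, , drop = FALSE]),
               mean(y[order(d)[1:3]]))
  expect_error(fitRegressor(modelSpec("knn", k = 15), X[1:10, ], y[1:10]),
               "training size")

  # stochastic learners are reproducible under a fixed seed
  rf1 <- fitRegressor(modelSpec("random_forest", seed = 9), X, y)
  rf2 <- fitRegressor(modelSpec("random_forest", seed = 9), X, y)
  expect_equal(predictRegressor(rf1, X), predictRegressor(rf2, X))
  ada1 <- fitRegressor(modelSpec("adaboost", seed = 9), X, y)
  ada2 <- fitRegressor(modelSpec("adaboost", seed = 9), X, y)
  expect_equal(predictRegressor(ada1, X), predictRegressor(ada2, X))
  expect_true(rSquared(y, predictRegressor(ada1, X)) > 0.5)
  lars <- fitRegressor(modelSpec("lars_cv", seed = 9), X, y)
  expect_equal(predictRegressor(lars, X), y, tolerance = 0.5)

  expect_error(predictRegressor(ols, X[, 1:2]), "dimension mismatch")
  expect_error(modelSpec("knn", k = 16), "k")
  expect_error(modelSpec("random_forest", nEstimators = 5), "nEstimators")
})

test_that("R-squared and RMSE follow their definitions", {
  y <- c(0, 1, 2)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(rSquared(y, c(0, 1, 1)), 0.5)
  expect_error(rSquared(c(3, 3), c(1, 2)), "constant")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(3)
  expect_gte(rmse(rnorm(10), rnorm(10)), 0)
})

test_that("Monte Carlo cross-validation recovers a noiseless linear signal", {
  es <- linearFixture()
  rep <- mccv(es, comboId = 1, spec = modelSpec("ols"),
              plan = splitPlan(seed = 4), nIter = 3)
  expect_equal(rep$meanR2, 1, tolerance = 1e-9)
  expect_equal(rep$meanRMSE, 0, tolerance = 1e-6)

  one <- mccv(es, comboId = 1, spec = modelSpec("ols"),
              plan = splitPlan(seed = 4), nIter = 1)
  expect_equal(one$meanR2, one$perIterationR2[1])

  # determinism under the master seed
  a <- mccv(es, comboId = 7, spec = modelSpec("knn", k = 3, seed = 6),
            plan = splitPlan(seed = 6), nIter = 2)
  b <- mccv(es, comboId = 7, spec = modelSpec("knn", k = 3, seed = 6),
            plan = splitPlan(seed = 6), nIter = 2)
  expect_identical(a$perIterationR2, b$perIterationR2)
  expect_equal(a$meanR2, mean(a$perIterationR2))
})

test_that("two datasets sharing ids and labels receive identical splits", {
  es <- linearFixture()
  scrambled <- EnzymeSet(
    stats::setNames(vapply(seqIds(es), function(i) randomSeq(30), ""),
                    seqIds(es)),
    ec = unname(ecNumbers(es)), topt = unname(toptValues(es)))
  p <- splitPlan(seed = 11)
  s1 <- stratifiedSplit(es, p)
  s2 <- stratifiedSplit(scrambled, p)
  expect_identical(seqIds(s1$test), seqIds(s2$test))
})

test_that("paired score comparison uses the exact signed-rank distribution", {
  set.seed(17)
  base <- runif(10)
  shifted <- base + seq(0.05, 0.5, length.out = 10)  # distinct positive diffs
  p <- comparePaired(shifted, base)
  expect_equal(p, 2 / 2^10, tolerance = 1e-12)

  mixed <- base + c(0.01, -0.01, 0.02, -0.02, 0.03,
                    -0.03, 0.04, -0.04, 0.05, -0.05)
  expect_gt(comparePaired(mixed, base), 0.05)

  expect_error(comparePaired(1:5, 1:4), "length")
  expect_error(comparePaired(base, base), "zero")
})

test_that("evaluation reports serialize with their manifest", {
  es <- linearFixture()
  rep <- mccv(es, comboId = 1, spec = modelSpec("ols"),
              plan = splitPlan(seed = 4), nIter = 2)
  f <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, f, manifest = list(dataset = "linearFixture"))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$meanR2, rep$meanR2)
  expect_equal(back$manifest$dataset, "linearFixture")
})
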