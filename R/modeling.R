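#' @include imbalance.R
NULL

#' Model specification for the regressor registry
#'
#' Five algorithms are registered, mirroring the fields usually compared
#' for sequence-based Topt regression: ordinary least squares
#' (\code{"ols"}), random forest (\code{"random_forest"}, 10-100 trees),
#' K-nearest neighbours (\code{"knn"}, uniform weights, Euclidean
#' distance, K in 1..15), AdaBoost.R2 over regression trees
#' (\code{"adaboost"}, 50 trees with at least two samples per leaf), and
#' cross-validated least-angle/lasso regression (\code{"lars_cv"}).
#'
#' @param algorithm one of \code{"knn"}, \code{"random_forest"},
#'   \code{"adaboost"}, \code{"ols"}, \code{"lars_cv"}.
#' @param k neighbour count for KNN; \code{NULL} (default) selects K in
#'   1..15 by an inner Monte Carlo cross-validation on the training
#'   partition, maximising mean R-squared.
#' @param nEstimators trees for the forest (10-100) or boosting rounds
#'   (fixed at 50 for AdaBoost).
#' @param minLeaf minimum samples per leaf for AdaBoost base trees.
#' @param seed seed for stochastic learners.
#' @return a list of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(algorithm = c("knn", "random_forest", "adaboost",
                                    "ols", "lars_cv"),
                      k = NULL, nEstimators = NULL, minLeaf = 2L,
                      seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!is.null(k)) stopifnot(k >= 1L, k <= 15L)
  if (algorithm == "random_forest") {
    if (is.null(nEstimators)) nEstimators <- 100L
    stopifnot(nEstimators >= 10L, nEstimators <= 100L)
  }
  if (algorithm == "adaboost") {
    if (is.null(nEstimators)) nEstimators <- 50L
  }
  structure(list(algorithm = algorithm, k = k,
                 nEstimators = nEstimators, minLeaf = as.integer(minLeaf),
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

#' Temperature-stratified split plan
#'
#' Topt values are binned into the ranges
#' \code{[0,30) [30,50) [50,65) [65,85) [85,100]} degrees C (half-open
#' except the last). The per-bin test draw defaults to a quarter of the
#' smallest bin, \code{max(1, floor(min count / 4))}, so every temperature
#' band is represented in both partitions.
#'
#' @param binEdges bin boundaries in degrees C.
#' @param perBinTestN override for the per-bin test count.
#' @param seed seed for the test draw.
#' @return a list of class \code{"SplitPlan"}.
#' @export
splitPlan <- function(binEdges = c(0, 30, 50, 65, 85, 100),
                      perBinTestN = NULL, seed = 1L) {
  stopifnot(length(binEdges) >= 2L, !is.unsorted(binEdges, strictly = TRUE))
  if (!is.null(perBinTestN)) stopifnot(perBinTestN >= 1L)
  structure(list(binEdges = binEdges, perBinTestN = perBinTestN,
                 seed = as.integer(seed)),
            class = "SplitPlan")
}

.binAssign <- function(y, edges) {
  if (any(y < edges[1L] | y > edges[length(edges)]))
    stop("Topt value(s) outside the bin range [",
         edges[1L], ", ", edges[length(edges)], "]")
  findInterval(y, edges, rightmost.closed = TRUE)
}

#' Stratified train/test indices over temperature bins
#'
#' @param y numeric Topt vector.
#' @param plan a \code{\link{splitPlan}}.
#' @return \code{list(trainIdx, testIdx, perBin)}; partitions are disjoint
#'   and cover \code{seq_along(y)}.
#' @export
stratifiedSplitIndices <- function(y, plan = splitPlan()) {
  bins <- .binAssign(y, plan$binEdges)
  nBins <- length(plan$binEdges) - 1L
  counts <- tabulate(bins, nbins = nBins)
  if (any(counts == 0L))
    stop(sprintf("empty temperature bin [%g, %g)",
                 plan$binEdges[which(counts == 0L)[1L]],
                 plan$binEdges[which(counts == 0L)[1L] + 1L]))
  perBin <- plan$perBinTestN
  if (is.null(perBin)) perBin <- max(1L, floor(min(counts) / 4))
  if (any(counts < perBin + 1L))
    stop("a bin is too small to leave training data after the test draw")
  set.seed(plan$seed)
  testIdx <- integer(0)
  for (b in seq_len(nBins)) {
    inBin <- which(bins == b)
    testIdx <- c(testIdx, sample(inBin, perBin))
  }
  testIdx <- sort(testIdx)
  list(trainIdx = setdiff(seq_along(y), testIdx), testIdx = testIdx,
       perBin = perBin)
}

#' Temperature-stratified dataset split
#'
#' @param dataset an \code{EnzymeSet} with Topt labels.
#' @param plan a \code{\link{splitPlan}}.
#' @return \code{list(train, test)} of \code{EnzymeSet}, plus the index
#'   lists from \code{\link{stratifiedSplitIndices}}.
#' @export
stratifiedSplit <- function(dataset, plan = splitPlan()) {
  stopifnot(is(dataset, "EnzymeSet"))
  y <- unname(toptValues(dataset))
  if (anyNA(y)) stop("every record needs a Topt label to be split")
  idx <- stratifiedSplitIndices(y, plan)
  list(train = dataset[idx$trainIdx], test = dataset[idx$testIdx],
       trainIdx = idx$trainIdx, testIdx = idx$testIdx, perBin = idx$perBin)
}

# ---- regressor registry ----------------------------------------------------

# AdaBoost.R2 (linear loss) over rpart regression trees
.adaboostR2 <- function(X, y, nEstimators = 50L, minLeaf = 2L, seed = 1L) {
  n <- nrow(X)
  df <- data.frame(.y = y, X)
  colnames(df) <- c(".y", paste0("V", seq_len(ncol(X))))
  ctrl <- rpart::rpart.control(minbucket = minLeaf, cp = 0.001, xval = 0L)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  set.seed(seed)
  for (m in seq_len(nEstimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        control = ctrl)
    pred <- predict(fit, df)
    err <- abs(pred - y)
    D <- max(err)
    if (D <= 0) {                       # perfect fit: keep it, stop boosting
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, log(1 / 1e-10))
      break
    }
    L <- err / D
    ebar <- sum(w * L)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, log(1 / max(beta, 1e-10)))
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  if (!length(trees)) {                 # degenerate: single unweighted tree
    trees <- list(rpart::rpart(.y ~ ., data = df, control = ctrl))
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, p = ncol(X)),
            class = "adaboostR2")
}

.predictAdaboostR2 <- function(model, X) {
  df <- data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(X)))
  preds <- vapply(model$trees, predict, numeric(nrow(df)), newdata = df)
  preds <- matrix(preds, nrow = nrow(df))
  w <- model$alphas
  # weighted median across base learners, per sample
  apply(preds, 1L, function(p) {
    ord <- order(p)
    cw <- cumsum(w[ord])
    p[ord][which(cw >= 0.5 * sum(w))[1L]]
  })
}

# inner Monte Carlo selection of K for KNN, maximising mean R-squared
.selectK <- function(X, y, kGrid = 1:15, nInner = 3L, seed = 1L,
                     binEdges = c(0, 30, 50, 65, 85, 100)) {
  kGrid <- kGrid[kGrid < length(y)]
  if (!length(kGrid)) kGrid <- 1L
  means <- vapply(kGrid, function(k) {
    r2 <- vapply(seq_len(nInner), function(it) {
      idx <- tryCatch(
        stratifiedSplitIndices(y, splitPlan(binEdges, seed = seed + it)),
        error = function(e) NULL)
      if (is.null(idx)) {               # tiny or one-band folds: random holdout
        set.seed(seed + it)
        test <- sample.int(length(y), max(2L, floor(length(y) / 5)))
        idx <- list(trainIdx = setdiff(seq_along(y), test), testIdx = test)
      }
      if (k >= length(idx$trainIdx)) return(NA_real_)
      fit <- caret::knnreg(X[idx$trainIdx, , drop = FALSE],
                           y[idx$trainIdx], k = k)
      pred <- predict(fit, X[idx$testIdx, , drop = FALSE])
      if (stats::sd(y[idx$testIdx]) == 0) return(NA_real_)
      rSquared(y[idx$testIdx], pred)
    }, 0)
    mean(r2, na.rm = TRUE)
  }, 0)
  kGrid[which.max(means)]
}

#' Fit a registered regressor
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param X standardized numeric feature matrix.
#' @param y numeric Topt labels, parallel to the rows of \code{X}.
#' @return a fitted model of class \code{"ToptModel"}; pass to
#'   \code{\link{predictRegressor}}.
#' @export
fitRegressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "ModelSpec"), nrow(X) == length(y))
  fit <- switch(spec$algorithm,
    knn = {
      k <- spec$k
      if (is.null(k)) k <- .selectK(X, y, seed = spec$seed)
      if (k > length(y)) stop("K cannot exceed the training size")
      list(model = caret::knnreg(X, y, k = k), k = k)
    },
    ols = {
      cf <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
      cf[is.na(cf)] <- 0               # collinear columns contribute nothing
      list(coef = cf)
    },
    random_forest = {
      set.seed(spec$seed)
      list(model = randomForest::randomForest(x = X, y = y,
                                              ntree = spec$nEstimators))
    },
    adaboost = {
      list(model = .adaboostR2(X, y, nEstimators = spec$nEstimators,
                               minLeaf = spec$minLeaf, seed = spec$seed))
    },
    lars_cv = {
      set.seed(spec$seed)
      nf <- max(3L, min(10L, length(y)))
      list(model = glmnet::cv.glmnet(X, y, alpha = 1, nfolds = nf))
    },
    stop("unknown algorithm: ", spec$algorithm))
  structure(c(fit, list(algorithm = spec$algorithm, p = ncol(X))),
            class = "ToptModel")
}

#' Predict from a fitted regressor
#'
#' @param model a \code{"ToptModel"} from \code{\link{fitRegressor}}.
#' @param X feature matrix with the training column count.
#' @return numeric vector of finite predictions.
#' @export
predictRegressor <- function(model, X) {
  stopifnot(inherits(model, "ToptModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$p)
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), model$p))
  out <- switch(model$algorithm,
    knn = predict(model$model, X),
    ols = drop(cbind(1, X) %*% model$coef),
    random_forest = {
      colnames(X) <- rownames(model$model$importance)
      unname(predict(model$model, X))
    },
    adaboost = .predictAdaboostR2(model$model, X),
    lars_cv = drop(predict(model$model, newx = X, s = "lambda.min")))
  stopifnot(all(is.finite(out)))
  as.numeric(out)
}

# ---- metrics ---------------------------------------------------------------

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot}; may be negative for models worse than the
#' mean predictor.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yHat predictions, parallel to \code{y}.
#' @return a number, at most 1.
#' @export
rSquared <- function(y, yHat) {
  stopifnot(length(y) == length(yHat), length(y) >= 2L)
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) stop("R-squared undefined for constant observations")
  1 - sum((y - yHat)^2) / ssTot
}

#' Root mean square error
#'
#' @inheritParams rSquared
#' @return non-negative number in the units of \code{y}.
#' @export
rmse <- function(y, yHat) {
  stopifnot(length(y) == length(yHat), length(y) >= 1L)
  sqrt(mean((y - yHat)^2))
}

# ---- Monte Carlo cross-validation ------------------------------------------

# per-stage seed derivation from one master seed; offsets are arbitrary
# fixed primes so stages draw independent streams
.stageSeed <- function(master, iteration, stage) {
  (master + 7919L * iteration + 104729L * stage) %% .Machine$integer.max
}

#' Monte Carlo cross-validation of a Topt regressor
#'
#' For each of \code{nIter} iterations: draw a fresh temperature-stratified
#' train/test split, oversample the rare domain of the training partition,
#' standardize the descriptor matrix with training-partition statistics
#' only, fit the regressor and score R-squared (and RMSE) on the untouched
#' test partition. Descriptors are computed once per record up front —
#' resampling duplicates whole records, so the duplicated feature rows are
#' identical to refeaturizing the resampled training set. Splits depend
#' only on the labels and the seed, so two datasets sharing record ids and
#' labels (e.g. full-sequence and conservation-stripped variants) receive
#' identical record-id splits under the same plan.
#'
#' @param dataset an \code{EnzymeSet} with Topt labels.
#' @param comboId descriptor combination (1-12).
#' @param spec a \code{\link{modelSpec}}.
#' @param plan a \code{\link{splitPlan}}; its seed is the master seed.
#' @param nIter number of iterations (default 10).
#' @param resampleConfig a \code{\link{relevanceConfig}}; its seed slot is
#'   rederived per iteration.
#' @param features optional precomputed \code{FeatureMatrix} for
#'   \code{dataset} (must be unstandardized).
#' @return a list of class \code{"EvalReport"}: per-iteration R-squared
#'   and RMSE, their means and standard deviations, and the configuration.
#' @export
mccv <- function(dataset, comboId, spec = modelSpec("knn"),
                 plan = splitPlan(), nIter = 10L,
                 resampleConfig = relevanceConfig(), features = NULL) {
  stopifnot(is(dataset, "EnzymeSet"))
  y <- unname(toptValues(dataset))
  if (anyNA(y)) stop("every record needs a Topt label")
  if (is.null(features)) features <- buildFeatureMatrix(dataset, comboId)
  stopifnot(!features@standardized)
  Xall <- featureValues(features)

  r2 <- rmseVec <- numeric(nIter)
  for (it in seq_len(nIter)) {
    iterPlan <- splitPlan(plan$binEdges, plan$perBinTestN,
                          seed = .stageSeed(plan$seed, it, 1L))
    idx <- tryCatch(stratifiedSplitIndices(y, iterPlan),
                    error = function(e)
                      stop("iteration ", it, ": ", conditionMessage(e)))
    cfg <- relevanceConfig(resampleConfig$cl, resampleConfig$ch,
                           resampleConfig$relevanceThreshold,
                           seed = .stageSeed(plan$seed, it, 2L))
    os <- randomOversample(idx$trainIdx, y[idx$trainIdx], cfg)
    trainRows <- idx$trainIdx[os$index]

    Xtr <- Xall[trainRows, , drop = FALSE]
    rownames(Xtr) <- make.unique(rownames(Xtr))
    center <- colMeans(Xtr)
    scale <- apply(Xtr, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    zs <- function(M) sweep(sweep(M, 2L, center, "-"), 2L, scale, "/")

    iterSpec <- spec
    iterSpec$seed <- .stageSeed(spec$seed, it, 3L)
    class(iterSpec) <- "ModelSpec"
    model <- fitRegressor(iterSpec, zs(Xtr), y[trainRows])
    pred <- predictRegressor(model, zs(Xall[idx$testIdx, , drop = FALSE]))
    r2[it] <- rSquared(y[idx$testIdx], pred)
    rmseVec[it] <- rmse(y[idx$testIdx], pred)
  }
  structure(list(perIterationR2 = r2, meanR2 = mean(r2),
                 sdR2 = stats::sd(r2), perIterationRMSE = rmseVec,
                 meanRMSE = mean(rmseVec), nIterations = nIter,
                 comboId = as.integer(comboId),
                 algorithm = spec$algorithm, seed = plan$seed),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "MCCV (%d iterations, %s, combo %d): mean R2 = %.3f (sd %.3f), mean RMSE = %.1f\n",
    x$nIterations, x$algorithm, x$comboId, x$meanR2, x$sdR2, x$meanRMSE))
  invisible(x)
}

#' Write an evaluation report (plus run manifest) as JSON
#'
#' @param report an \code{EvalReport}.
#' @param path output path.
#' @param manifest optional named list appended under \code{$manifest}.
#' @export
writeEvalReport <- function(report, path, manifest = list()) {
  out <- unclass(report)
  out$manifest <- manifest
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Paired comparison of per-iteration scores
#'
#' Two-sided exact Wilcoxon signed-rank test on paired per-iteration
#' R-squared scores of two models evaluated on identical splits.
#'
#' @param scoresA,scoresB equal-length numeric vectors (length >= 5).
#' @return the p-value.
#' @export
comparePaired <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("paired score lists differ in length")
  stopifnot(length(scoresA) >= 5L)
  d <- scoresA - scoresB
  if (all(d == 0)) stop("all paired differences are zero; test undefined")
  suppressWarnings(
    stats::wilcox.test(scoresA, scoresB, paired = TRUE,
                       exact = TRUE)$p.value)
}
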