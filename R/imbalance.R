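#' @include features.R
NULL

#' Rare-domain configuration for imbalanced Topt regression
#'
#' Topt values below \code{cl} or above \code{ch} degrees C form the rare
#' domain; everything else (boundaries included) is the normal domain. The
#' defaults cl = 21 and ch = 64 bracket the mesophilic bulk of measured
#' optima. \code{relevanceThreshold} is recorded for interface
#' compatibility with relevance-based resamplers; the hard cutoffs govern
#' the labels here.
#'
#' @param cl,ch lower / upper control temperatures in degrees C.
#' @param relevanceThreshold relevance cutoff in (0, 1), recorded only.
#' @param seed integer seed for the resampler.
#' @return a list of class \code{"RelevanceConfig"}.
#' @export
relevanceConfig <- function(cl = 21, ch = 64, relevanceThreshold = 0.5,
                            seed = 1L) {
  stopifnot(cl < ch, relevanceThreshold > 0, relevanceThreshold < 1)
  structure(list(cl = cl, ch = ch,
                 relevanceThreshold = relevanceThreshold,
                 seed = as.integer(seed)),
            class = "RelevanceConfig")
}

#' Label temperature observations as rare or normal
#'
#' @param y numeric vector of Topt values (degrees C).
#' @param config a \code{\link{relevanceConfig}}.
#' @return character vector of \code{"rare"} / \code{"normal"} labels;
#'   values equal to a control temperature are normal.
#' @examples
#' domainLabels(c(10, 40, 90), relevanceConfig())  # rare normal rare
#' @export
domainLabels <- function(y, config = relevanceConfig()) {
  out <- rep("normal", length(y))
  out[y < config$cl | y > config$ch] <- "rare"
  out
}

#' Randomly oversample the rare temperature domain
#'
#' Rare-domain rows are resampled uniformly with replacement (seeded)
#' until the rare count equals the normal count; normal rows pass through
#' unchanged; the combined output is then deterministically shuffled.
#' Every output row is an exact copy of an input row — no interpolation.
#' With no rare rows the input is returned unchanged.
#'
#' @param X matrix (or \code{FeatureMatrix}) of predictors, rows parallel
#'   to \code{y}. May also be an index vector standing in for rows.
#' @param y numeric Topt vector.
#' @param config a \code{\link{relevanceConfig}} (provides cutoffs and
#'   seed).
#' @param fraction optional override: sample only
#'   \code{fraction * deficit} additional rare rows instead of matching
#'   the normal count exactly.
#' @return \code{list(X, y, index)} where \code{index} maps every output
#'   row to its source row in the input.
#' @export
randomOversample <- function(X, y, config = relevanceConfig(),
                             fraction = 1.0) {
  fm <- NULL
  if (is(X, "FeatureMatrix")) {
    fm <- X
    X <- featureValues(X)
  }
  vecX <- is.null(dim(X))
  nrows <- if (vecX) length(X) else nrow(X)
  stopifnot(nrows == length(y))
  labels <- domainLabels(y, config)
  normalIdx <- which(labels == "normal")
  rareIdx <- which(labels == "rare")
  if (!length(normalIdx)) stop("no normal-domain samples to balance against")
  if (!length(rareIdx)) {
    idx <- seq_along(y)
  } else {
    deficit <- length(normalIdx) - length(rareIdx)
    extra <- integer(0)
    if (deficit > 0L) {
      nDraw <- as.integer(round(fraction * deficit))
      set.seed(config$seed)
      extra <- sample(rareIdx, nDraw, replace = TRUE)
    }
    idx <- c(seq_along(y), extra)
    set.seed(config$seed + 1L)
    idx <- idx[sample.int(length(idx))]
  }
  outX <- if (vecX) X[idx] else X[idx, , drop = FALSE]
  if (!is.null(fm)) {
    rn <- rownames(outX)
    if (!is.null(rn)) rownames(outX) <- make.unique(rn)
    outX <- new("FeatureMatrix", values = outX, comboId = fm@comboId,
                standardized = fm@standardized, center = fm@center,
                scale = fm@scale)
  }
  list(X = outX, y = y[idx], index = idx)
}
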