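#' @include seqdata.R
NULL

#' Parameters for a synthetic protein family
#'
#' A family shares a fixed scaffold of residues at fixed, interleaved
#' positions (these become the fully conserved alignment columns) while
#' the remaining, variable positions differ between members. Topt labels
#' can be attached as a function of variable-region composition.
#'
#' @param nMembers family size.
#' @param scaffoldLength number of conserved scaffold residues.
#' @param variableLength number of variable positions.
#' @param mutationRate per-site substitution probability at variable
#'   positions, relative to the family's variable-region consensus.
#' @param toptModel list with \code{baseline} (degrees C), \code{weight}
#'   (degrees C per unit class fraction), \code{class} (designated residue
#'   class, default \code{c("R","K")}) and \code{noiseSD} (degrees C).
#' @param scaffoldClassFraction expected fraction of scaffold residues
#'   drawn from the designated class (NULL = uniform scaffold).
#' @param ecLabel pseudo-EC label for the family (EC 3.1.3.X namespace
#'   formatting, no real enzyme implied).
#' @param seed integer seed.
#' @return a list of class \code{"FamilyParams"}.
#' @export
familyParams <- function(nMembers = 10L, scaffoldLength = 150L,
                         variableLength = 50L, mutationRate = 0.5,
                         toptModel = list(baseline = 15, weight = 80,
                                          class = c("R", "K"),
                                          noiseSD = 4),
                         scaffoldClassFraction = NULL,
                         ecLabel = "3.1.3.1", seed = 1L) {
  stopifnot(nMembers >= 1L, scaffoldLength >= 1L, variableLength >= 1L,
            mutationRate >= 0, mutationRate <= 1,
            toptModel$noiseSD >= 0)
  structure(list(nMembers = as.integer(nMembers),
                 scaffoldLength = as.integer(scaffoldLength),
                 variableLength = as.integer(variableLength),
                 mutationRate = mutationRate, toptModel = toptModel,
                 scaffoldClassFraction = scaffoldClassFraction,
                 ecLabel = ecLabel, seed = as.integer(seed)),
            class = "FamilyParams")
}

.drawScaffoldResidues <- function(n, classFraction, class) {
  if (is.null(classFraction)) return(sample(AA_CANONICAL, n, replace = TRUE))
  others <- setdiff(AA_CANONICAL, class)
  inClass <- stats::runif(n) < classFraction
  out <- character(n)
  out[inClass] <- sample(class, sum(inClass), replace = TRUE)
  out[!inClass] <- sample(others, sum(!inClass), replace = TRUE)
  out
}

# guarantee every variable column carries >= 2 distinct residues so that
# conserved-column detection recovers exactly the scaffold
.forceVariableDiff <- function(varMat) {
  if (nrow(varMat) < 2L) return(varMat)
  for (j in seq_len(ncol(varMat))) {
    if (length(unique(varMat[, j])) == 1L) {
      alt <- setdiff(AA_CANONICAL, varMat[1L, j])
      varMat[sample.int(nrow(varMat), 1L), j] <- sample(alt, 1L)
    }
  }
  varMat
}

#' Generate one synthetic protein family
#'
#' Members are gap-free and of identical length; scaffold residues occupy
#' the same columns in every member, so those columns are the ground-truth
#' conserved set. Variable positions start from a family consensus and
#' are substituted independently with probability \code{mutationRate}.
#' With \code{forceVariableDiff} every variable column is guaranteed to
#' carry at least two distinct residues (families of one member excepted),
#' making conserved-column recovery exact.
#'
#' @param params a \code{\link{familyParams}}.
#' @param forceVariableDiff logical (default \code{FALSE}).
#' @param idPrefix record-id prefix.
#' @return list of class \code{"SyntheticFamily"}: \code{set} (an
#'   \code{EnzymeSet}), \code{conservedPositions} (0-based column indices
#'   of the scaffold), \code{scaffoldResidues}, and \code{params}.
#' @export
generateFamily <- function(params, forceVariableDiff = FALSE,
                           idPrefix = "F") {
  stopifnot(inherits(params, "FamilyParams"))
  set.seed(params$seed)
  L <- params$scaffoldLength + params$variableLength
  scaffoldPos <- sort(sample.int(L, params$scaffoldLength))
  cls <- params$toptModel$class
  scaffold <- .drawScaffoldResidues(params$scaffoldLength,
                                    params$scaffoldClassFraction, cls)
  consensus <- sample(AA_CANONICAL, params$variableLength, replace = TRUE)
  varMat <- matrix(rep(consensus, each = params$nMembers),
                   nrow = params$nMembers)
  mutate <- matrix(stats::runif(length(varMat)) < params$mutationRate,
                   nrow = params$nMembers)
  if (any(mutate))
    varMat[mutate] <- sample(AA_CANONICAL, sum(mutate), replace = TRUE)
  if (forceVariableDiff) varMat <- .forceVariableDiff(varMat)

  seqs <- vapply(seq_len(params$nMembers), function(i) {
    chars <- character(L)
    chars[scaffoldPos] <- scaffold
    chars[-scaffoldPos] <- varMat[i, ]
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- sprintf("%s_m%03d", idPrefix, seq_len(params$nMembers))
  set <- EnzymeSet(seqs, ec = rep(params$ecLabel, params$nMembers),
                   name = idPrefix)
  structure(list(set = set, conservedPositions = scaffoldPos - 1L,
                 scaffoldResidues = scaffold, params = params),
            class = "SyntheticFamily")
}

# member-specific designated-class probability: mostly a Beta bulk with a
# small hot tail so every temperature bin is populated
.drawClassProb <- function(n) {
  hot <- stats::runif(n) < 0.05
  p <- stats::rbeta(n, 2.5, 4.5)
  p[hot] <- stats::runif(sum(hot), 0.85, 1)
  p
}

#' Generate a labeled multi-family Topt benchmark
#'
#' Builds \code{nFamilies} gap-free families with distinct pseudo-EC
#' labels. Each member's variable positions are drawn from the designated
#' residue class with a member-specific probability p (Beta-distributed
#' bulk with a small hot tail), and its label is
#' \code{Topt = baseline + weight * (observed class fraction among
#' variable positions) + Gaussian noise} — the Topt signal lives only in
#' the variable region. Family scaffolds differ in designated-class
#' content (evenly spaced fractions), so full-sequence composition
#' confounds scaffold with signal while the stripped sequences do not.
#' The marginal Topt histogram is unimodal with its mode in 30-50 degrees
#' C and under 5 percent of mass above 85 degrees C; rare tails below 21
#' and above 64 degrees C are present.
#'
#' @param nFamilies number of families (default 5).
#' @param membersPerFamily members per family (default 50).
#' @param scaffoldLength,variableLength region sizes (defaults 150, 50).
#' @param baseline,weight,noiseSD label-model parameters (defaults 15
#'   degrees C, 80 degrees C per unit fraction, 4 degrees C).
#' @param designatedClass residue class carrying the signal (default
#'   \code{c("R","K")}).
#' @param scaffoldClassFractions per-family scaffold designated-class
#'   content; default evenly spaced over [0.05, 0.6].
#' @param seed master seed.
#' @return list of class \code{"SyntheticBenchmark"}: \code{set} (labeled
#'   \code{EnzymeSet} over all families), \code{families} (list of
#'   \code{SyntheticFamily}-like ground truth), \code{classFraction}
#'   (per-member observed signal fraction), and the parameters.
#' @export
generateLabeledBenchmark <- function(nFamilies = 5L, membersPerFamily = 50L,
                                     scaffoldLength = 150L,
                                     variableLength = 50L, baseline = 15,
                                     weight = 80, noiseSD = 4,
                                     designatedClass = c("R", "K"),
                                     scaffoldClassFractions = NULL,
                                     seed = 1L) {
  set.seed(seed)
  if (is.null(scaffoldClassFractions))
    scaffoldClassFractions <- seq(0.05, 0.6, length.out = nFamilies)
  stopifnot(length(scaffoldClassFractions) == nFamilies)
  others <- setdiff(AA_CANONICAL, designatedClass)
  L <- scaffoldLength + variableLength

  families <- vector("list", nFamilies)
  allSeqs <- character(0)
  allEc <- character(0)
  allTopt <- numeric(0)
  allFrac <- numeric(0)
  for (f in seq_len(nFamilies)) {
    scaffoldPos <- sort(sample.int(L, scaffoldLength))
    scaffold <- .drawScaffoldResidues(scaffoldLength,
                                      scaffoldClassFractions[f],
                                      designatedClass)
    p <- .drawClassProb(membersPerFamily)
    varMat <- matrix("", membersPerFamily, variableLength)
    for (i in seq_len(membersPerFamily)) {
      inClass <- stats::runif(variableLength) < p[i]
      row <- character(variableLength)
      row[inClass] <- sample(designatedClass, sum(inClass), replace = TRUE)
      row[!inClass] <- sample(others, sum(!inClass), replace = TRUE)
      varMat[i, ] <- row
    }
    varMat <- .forceVariableDiff(varMat)
    frac <- rowMeans(matrix(varMat %in% designatedClass,
                            membersPerFamily, variableLength))
    topt <- baseline + weight * frac +
      stats::rnorm(membersPerFamily, 0, noiseSD)
    topt <- pmin(pmax(topt, 2), 99)

    ids <- sprintf("FAM%d_m%03d", f, seq_len(membersPerFamily))
    seqs <- vapply(seq_len(membersPerFamily), function(i) {
      chars <- character(L)
      chars[scaffoldPos] <- scaffold
      chars[-scaffoldPos] <- varMat[i, ]
      paste(chars, collapse = "")
    }, "")
    names(seqs) <- ids
    allSeqs <- c(allSeqs, seqs)
    allEc <- c(allEc, rep(sprintf("3.1.3.%d", f), membersPerFamily))
    allTopt <- c(allTopt, topt)
    allFrac <- c(allFrac, frac)
    families[[f]] <- list(conservedPositions = scaffoldPos - 1L,
                          scaffoldResidues = scaffold,
                          ec = sprintf("3.1.3.%d", f))
  }
  set <- EnzymeSet(allSeqs, ec = allEc, topt = allTopt,
                   name = sprintf("benchmark_seed%d", seed))
  structure(list(set = set, families = families,
                 classFraction = stats::setNames(allFrac, names(allSeqs)),
                 baseline = baseline, weight = weight, noiseSD = noiseSD,
                 designatedClass = designatedClass, seed = seed),
            class = "SyntheticBenchmark")
}

#' Write a synthetic benchmark's artifacts
#'
#' Emits the FASTA, the labeled dataset table, and a ground-truth TSV of
#' per-family conserved scaffold positions and the generating weights.
#'
#' @param benchmark a \code{SyntheticBenchmark}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFastaSet(benchmark$set, file.path(dir, "benchmark.fasta"))
  writeDatasetTable(benchmark$set, file.path(dir, "benchmark.csv"))
  gt <- do.call(rbind, lapply(benchmark$families, function(f) {
    data.frame(ec = f$ec,
               conservedPositions = paste(f$conservedPositions,
                                          collapse = ","),
               stringsAsFactors = FALSE)
  }))
  gt$baseline <- benchmark$baseline
  gt$weight <- benchmark$weight
  gt$noiseSD <- benchmark$noiseSD
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
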