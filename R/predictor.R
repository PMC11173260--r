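#' @include modeling.R ssn.R conservation.R
NULL

#' Train an end-to-end Topt prediction bundle
#'
#' Runs the full training pipeline: EC grouping, baseline filtering,
#' per-group alignment and conserved-residue stripping (with sequence
#' similarity network sub-grouping of low-conservation families),
#' rare-domain oversampling, descriptor extraction and standardization,
#' and a final fit on all processed training data. The returned bundle
#' carries the reference alignments and conserved maps needed to process
#' a novel query identically.
#'
#' @param dataset an \code{EnzymeSet} with EC and Topt annotation on every
#'   record.
#' @param comboId descriptor combination (default 7: amino acid
#'   frequencies + molecular weight).
#' @param spec a \code{\link{modelSpec}} (default KNN).
#' @param mode train on conserved-stripped (\code{"rcaa"}, default) or
#'   intact (\code{"full"}) sequences.
#' @param minLen,minRcaaLen length floors for raw and stripped sequences.
#' @param resampleConfig a \code{\link{relevanceConfig}}.
#' @param ssnCandidates candidate similarity thresholds for the SSN
#'   fallback.
#' @param threshold conservation threshold (default 1).
#' @param ... alignment arguments passed to \code{\link{stripGroup}}.
#' @return a \code{\linkS4class{ToptBundle}}.
#' @export
trainBundle <- function(dataset, comboId = 7L, spec = modelSpec("knn"),
                        mode = c("rcaa", "full"), minLen = 50L,
                        minRcaaLen = 50L,
                        resampleConfig = relevanceConfig(),
                        ssnCandidates = seq(30, 90, by = 10),
                        threshold = 1.0, ...) {
  mode <- match.arg(mode)
  comboId <- as.integer(comboId)
  if (is.na(comboId) || comboId < 1L || comboId > 12L)
    stop("comboId must be in 1..12")
  stopifnot(is(dataset, "EnzymeSet"))
  if (anyNA(ecNumbers(dataset)))
    stop("stage grouping: every record needs an EC number")
  if (anyNA(toptValues(dataset)))
    stop("stage grouping: every record needs a Topt label")

  filt <- applyBaselineFilters(groupByEC(dataset), minLen = minLen)
  if (!length(filt$groups)) stop("stage filtering: no groups survive")

  groupsOut <- list()
  rcaaSets <- list()
  origSets <- list()
  removalLog <- filt$log
  processGroup <- function(g, allowSSN = TRUE) {
    res <- tryCatch(stripGroup(g, minRcaaLen = minRcaaLen,
                               threshold = threshold, ...),
                    error = function(e)
                      stop("stage conservation [", setName(g), "]: ",
                           conditionMessage(e)))
    if (res$lowConservation && allowSSN && length(g) > 2L) {
      sub <- ssnSubgroups(g, candidates = ssnCandidates)
      if (length(sub$removed))
        removalLog <<- rbind(removalLog, data.frame(
          id = sub$removed, group = setName(g),
          reason = "singleton-ssn-cluster", stringsAsFactors = FALSE))
      if (length(sub$subgroups)) {
        for (sg in sub$subgroups) processGroup(sg, allowSSN = FALSE)
        return(invisible(NULL))
      }
    }
    if (length(res$rcaa) >= 2L) {
      key <- setName(g)
      groupsOut[[key]] <<- list(alignment = res$alignment, map = res$map)
      rcaaSets[[key]] <<- res$rcaa
      origSets[[key]] <<- res$original
    }
    if (nrow(res$log)) removalLog <<- rbind(removalLog, res$log)
    invisible(NULL)
  }
  for (g in filt$groups) processGroup(g)
  if (!length(origSets)) stop("stage conservation: no groups survive")

  originals <- combineSets(origSets, name = "training_full")
  rcaa <- combineSets(rcaaSets, name = "training_rcaa")
  trainSet <- if (mode == "rcaa") rcaa else originals
  groupOf <- stats::setNames(
    rep(names(origSets), vapply(origSets, length, 0L)),
    unlist(lapply(origSets, seqIds)))

  y <- unname(toptValues(trainSet))
  features <- buildFeatureMatrix(trainSet, comboId)
  cfg <- resampleConfig
  os <- randomOversample(seq_along(y), y, cfg)
  Xtr <- featureValues(features)[os$X, , drop = FALSE]
  rownames(Xtr) <- make.unique(rownames(Xtr))
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xz <- sweep(sweep(Xtr, 2L, center, "-"), 2L, scale, "/")

  model <- fitRegressor(spec, Xz, os$y)
  specOut <- spec
  if (spec$algorithm == "knn" && is.null(spec$k)) specOut$k <- model$k
  manifest <- list(
    nInput = length(dataset), nTraining = length(trainSet),
    comboId = comboId, mode = mode, threshold = threshold,
    minLen = minLen, minRcaaLen = minRcaaLen,
    resampleConfig = unclass(cfg), spec = unclass(specOut),
    groupOf = as.list(groupOf),
    removals = removalLog)

  new("ToptBundle", comboId = comboId, spec = unclass(specOut),
      model = model, scaler = list(center = center, scale = scale),
      trainX = Xz, trainY = os$y, groups = groupsOut,
      originals = originals, rcaa = rcaa, mode = mode,
      manifest = manifest)
}

setMethod("show", "ToptBundle", function(object) {
  cat(sprintf(
    "ToptBundle (%s mode): %s on combo %d | %d training record(s), %d group(s)\n",
    object@mode, object@spec$algorithm, object@comboId,
    length(object@originals), length(object@groups)))
  invisible(NULL)
})

#' Assign an EC number to a query sequence
#'
#' The EC number of the training record with the highest global-alignment
#' percent identity to the query; ties break toward the higher alignment
#' score, then the lexicographically smallest record id. Best identities
#' below \code{floor} are flagged.
#'
#' @param query a residue string (or single-record \code{EnzymeSet}).
#' @param bundle a trained \code{\linkS4class{ToptBundle}}.
#' @param floor identity (percent) below which the assignment is flagged.
#' @return list with \code{ec}, \code{bestId}, \code{identity},
#'   \code{score} and \code{flag} (\code{""} or \code{"low-identity"}).
#' @export
assignEC <- function(query, bundle, floor = 20) {
  stopifnot(is(bundle, "ToptBundle"))
  if (is(query, "EnzymeSet")) {
    stopifnot(length(query) == 1L)
    query <- as.character(sequences(query))
  }
  validateResidues(query)
  refs <- bundle@originals
  if (!length(refs)) stop("bundle has no reference sequences")
  ids <- seqIds(refs)
  seqs <- as.character(sequences(refs))
  sub <- .getSubMatrix("BLOSUM62")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(seqs))),
    Biostrings::AAStringSet(seqs),
    substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  idents <- Biostrings::pid(pa, type = "PID1")
  scores <- Biostrings::score(pa)
  ord <- order(-idents, -scores, ids)
  best <- ord[1L]
  list(ec = unname(ecNumbers(refs)[best]), bestId = ids[best],
       identity = idents[best], score = scores[best],
       flag = if (idents[best] < floor) "low-identity" else "")
}

# majority (non-gap) residue of every alignment column; alphabetical
# tie-break for determinism
.columnConsensus <- function(alignment) {
  chars <- do.call(rbind, strsplit(msaRows(alignment), ""))
  vapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    col <- col[col != "-"]
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1L]
  }, "")
}

# map a query onto a group's alignment: align the query against the
# full-width column consensus (so repeated residues keep their positional
# context), then take the 0-based query positions that sit in a conserved
# column AND carry its conserved residue; conserved columns the query does
# not match are counted as mismatches
.queryConservedPositions <- function(query, map, alignment) {
  if (!length(map@columns))
    return(list(positions = integer(0), mismatches = 0L))
  consensus <- paste(.columnConsensus(alignment), collapse = "")
  al <- pairwiseGlobalAlign(query, consensus)
  qc <- strsplit(al$alignedA, "")[[1L]]
  cc <- strsplit(al$alignedB, "")[[1L]]
  qpos <- cumsum(qc != "-") - 1L
  cpos <- cumsum(cc != "-") - 1L
  consResidue <- stats::setNames(map@residues, map@columns)
  inCons <- cc != "-" & cpos %in% map@columns
  hit <- inCons & qc != "-" & qc == consResidue[as.character(cpos)]
  list(positions = qpos[which(hit)],
       mismatches = length(map@columns) - sum(hit))
}

#' Predict Topt for novel sequences
#'
#' For each query: assign an EC group by nearest training homologue; in
#' \code{"rcaa"} mode, align the query against that group's conserved
#' consensus, strip the query positions that carry the conserved residues
#' (conserved columns the query does not match are reported as mismatch
#' flags, not stripped), then featurize, scale with the bundle's training
#' scaler and predict. In \code{"full"} mode the intact sequence is
#' featurized.
#'
#' @param queries an \code{EnzymeSet} (EC/Topt annotation not required).
#' @param bundle a trained \code{\linkS4class{ToptBundle}}.
#' @param mode \code{"rcaa"} or \code{"full"}; defaults to the bundle's
#'   training mode.
#' @param floor identity floor passed to \code{\link{assignEC}}.
#' @return data.frame with columns id, ec, bestHit, identity,
#'   predictedTopt (degrees C), conservedMismatches, flags.
#' @export
predictTopt <- function(queries, bundle, mode = NULL, floor = 20) {
  stopifnot(is(queries, "EnzymeSet"), is(bundle, "ToptBundle"))
  if (is.null(mode)) mode <- bundle@mode
  mode <- match.arg(mode, c("rcaa", "full"))
  groupOf <- unlist(bundle@manifest$groupOf)
  rows <- lapply(seqIds(queries), function(id) {
    seq <- as.character(sequences(queries)[id])
    hit <- assignEC(seq, bundle, floor = floor)
    mismatches <- 0L
    flags <- hit$flag
    featSeq <- seq
    if (mode == "rcaa") {
      key <- groupOf[[hit$bestId]]
      grp <- bundle@groups[[key]]
      if (is.null(grp))
        stop("assigned group '", key, "' absent from bundle")
      qc <- .queryConservedPositions(seq, grp$map, grp$alignment)
      mismatches <- qc$mismatches
      if (mismatches > 0L)
        flags <- paste(c(flags[nzchar(flags)], "conserved-mismatch"),
                       collapse = ";")
      stripped <- stripConserved(seq, qc$positions)
      if (nchar(stripped) >= 3L) {
        featSeq <- stripped
      } else {
        flags <- paste(c(flags[nzchar(flags)], "stripped-too-short"),
                       collapse = ";")
      }
    }
    fv <- buildFeatureMatrix(EnzymeSet(stats::setNames(featSeq, id)),
                             bundle@comboId)
    x <- sweep(sweep(featureValues(fv), 2L, bundle@scaler$center, "-"),
               2L, bundle@scaler$scale, "/")
    pred <- predictRegressor(bundle@model, x)
    data.frame(id = id, ec = hit$ec, bestHit = hit$bestId,
               identity = hit$identity, predictedTopt = pred,
               conservedMismatches = mismatches,
               flags = if (nzchar(paste(flags, collapse = ""))) {
                 paste(flags, collapse = ";")
               } else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save a trained bundle as an auditable directory
#'
#' The bundle is written as plain text: a JSON manifest (configuration,
#' scaler, labels, resolved hyperparameters), the standardized training
#' matrix as TSV, the training datasets as tables, and per-group aligned
#' FASTA references. \code{\link{loadBundle}} refits the regressor
#' deterministically from these artifacts.
#'
#' @param bundle a \code{ToptBundle}.
#' @param dir output directory (created; must not already contain a
#'   bundle).
#' @return \code{dir}, invisibly.
#' @export
saveBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "ToptBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "groups"), showWarnings = FALSE)
  manifest <- list(
    comboId = bundle@comboId, mode = bundle@mode, spec = bundle@spec,
    scaler = bundle@scaler, trainY = bundle@trainY,
    trainIds = rownames(bundle@trainX),
    groupOf = bundle@manifest$groupOf,
    threshold = bundle@manifest$threshold,
    groups = names(bundle@groups),
    manifest = bundle@manifest[c("nInput", "nTraining", "minLen",
                                 "minRcaaLen", "resampleConfig")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  fm <- new("FeatureMatrix", values = bundle@trainX,
            comboId = bundle@comboId, standardized = FALSE,
            center = numeric(0), scale = numeric(0))
  writeFeatureMatrix(fm, file.path(dir, "trainX.tsv"))
  writeDatasetTable(bundle@originals, file.path(dir, "originals.csv"))
  writeDatasetTable(bundle@rcaa, file.path(dir, "rcaa.csv"))
  for (key in names(bundle@groups)) {
    safe <- gsub("[^A-Za-z0-9._#-]", "_", key)
    writeFastaSet(bundle@groups[[key]]$alignment,
                  file.path(dir, "groups", paste0(safe, ".aln.fasta")))
  }
  invisible(dir)
}

#' @rdname saveBundle
#' @param dir a directory written by \code{saveBundle}.
#' @export
loadBundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fm <- readFeatureMatrix(file.path(dir, "trainX.tsv"),
                          comboId = manifest$comboId)
  trainX <- featureValues(fm)
  trainY <- as.numeric(manifest$trainY)
  spec <- manifest$spec
  if (is.null(spec$k)) spec["k"] <- list(NULL)
  if (is.null(spec$nEstimators)) spec["nEstimators"] <- list(NULL)
  class(spec) <- "ModelSpec"
  model <- fitRegressor(spec, trainX, trainY)
  groups <- list()
  threshold <- manifest$threshold %||% 1.0
  for (key in manifest$groups) {
    safe <- gsub("[^A-Za-z0-9._#-]", "_", key)
    aln <- readAlignedFasta(file.path(dir, "groups",
                                      paste0(safe, ".aln.fasta")))
    groups[[key]] <- list(alignment = aln,
                          map = findConservedColumns(aln, threshold))
  }
  originals <- readDatasetTable(file.path(dir, "originals.csv"),
                                name = "training_full")
  rcaa <- readDatasetTable(file.path(dir, "rcaa.csv"),
                           name = "training_rcaa")
  new("ToptBundle", comboId = as.integer(manifest$comboId),
      spec = unclass(spec), model = model,
      scaler = list(
        center = stats::setNames(as.numeric(manifest$scaler$center),
                                 colnames(trainX)),
        scale = stats::setNames(as.numeric(manifest$scaler$scale),
                                colnames(trainX))),
      trainX = trainX, trainY = trainY, groups = groups,
      originals = originals, rcaa = rcaa, mode = manifest$mode,
      manifest = list(groupOf = as.list(unlist(manifest$groupOf)),
                      threshold = threshold,
                      nInput = manifest$manifest$nInput,
                      nTraining = manifest$manifest$nTraining))
}
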