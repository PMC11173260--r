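#' @include align.R
NULL

#' @rdname ConservedMap-class
setMethod("conservedColumns", "ConservedMap", function(x) x@columns)

#' @rdname ConservedMap-class
setMethod("conservedResidues", "ConservedMap", function(x) {
  stats::setNames(x@residues, x@columns)
})

#' @rdname ConservedMap-class
setMethod("conservedPositions", "ConservedMap", function(x) x@positions)

setMethod("show", "ConservedMap", function(object) {
  cat(sprintf("ConservedMap: %d conserved column(s) of %d (threshold %.2f)\n",
              length(object@columns), object@width, object@threshold))
  invisible(NULL)
})

#' Identify conserved alignment columns
#'
#' A column is conserved when the fraction of rows sharing one identical
#' non-gap residue is at least \code{threshold}. At the default threshold
#' of 1 this requires every row to carry the same residue and no row to
#' carry a gap, so the conserved position exists in every member sequence.
#' For each row the 0-based ungapped positions of the residues in the
#' conserved columns are computed by counting non-gap characters to the
#' left; at thresholds below 1 a row contributes a position only for
#' columns where it actually carries the consensus residue.
#'
#' @param msa a \code{\linkS4class{ProteinMSA}}.
#' @param threshold conservation fraction in (0, 1]; default 1.
#' @return a \code{\linkS4class{ConservedMap}}.
#' @examples
#' msa <- asProteinMSA(c(a = "ACD", b = "ACE"))
#' conservedColumns(findConservedColumns(msa))  # 0 1
#' @export
findConservedColumns <- function(msa, threshold = 1.0) {
  stopifnot(is(msa, "ProteinMSA"), threshold > 0, threshold <= 1)
  rows <- msaRows(msa)
  chars <- do.call(rbind, strsplit(rows, ""))
  nrows <- nrow(chars)
  width <- ncol(chars)

  cols <- integer(0)
  residues <- character(0)
  for (j in seq_len(width)) {
    col <- chars[, j]
    nongap <- col[col != "-"]
    if (!length(nongap)) next
    tab <- sort(table(nongap), decreasing = TRUE)
    # ties broken alphabetically for a deterministic consensus residue
    best <- names(tab)[order(-tab, names(tab))][1L]
    if (sum(col == best) / nrows >= threshold) {
      cols <- c(cols, j - 1L)
      residues <- c(residues, best)
    }
  }

  positions <- vector("list", nrows)
  names(positions) <- rownames(chars) <- names(rows)
  for (i in seq_len(nrows)) {
    ungapped <- cumsum(chars[i, ] != "-") - 1L  # 0-based position per column
    keep <- cols[chars[i, cols + 1L] == residues]
    positions[[i]] <- ungapped[keep + 1L]
  }
  new("ConservedMap", columns = cols, residues = residues,
      positions = positions, width = width, threshold = threshold)
}

#' Remove the residues at given positions from a sequence
#'
#' @param seq residue string.
#' @param positions sorted set of 0-based positions within
#'   \code{[0, nchar(seq))}.
#' @return the subsequence at the non-listed positions, order preserved.
#' @examples
#' stripConserved("ACDE", c(0, 1))  # "DE"
#' @export
stripConserved <- function(seq, positions) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!length(positions)) return(seq)
  positions <- as.integer(positions)
  if (min(positions) < 0L || max(positions) >= nchar(seq))
    stop("position outside [0, ", nchar(seq), ")")
  chars <- strsplit(seq, "")[[1L]]
  paste(chars[-(positions + 1L)], collapse = "")
}

#' Align a group and strip its conserved residues
#'
#' Aligns an EC group (unless a pre-computed alignment is supplied),
#' identifies the fully conserved columns, removes the corresponding
#' residues from every member, and drops members whose stripped sequence
#' falls below \code{minRcaaLen}. The returned original set contains
#' exactly the surviving members, so full-sequence and stripped-sequence
#' models can be evaluated on identical record splits. When fewer than
#' \code{minConserved} columns are conserved the result carries a
#' low-conservation flag so the caller can sub-group the family through a
#' sequence similarity network instead.
#'
#' @param group an \code{EnzymeSet} of at least two members.
#' @param minRcaaLen minimum stripped-sequence length retained (default 50,
#'   the same floor applied to raw sequences).
#' @param minConserved conserved-column count below which the group is
#'   flagged low-conservation; default \code{NULL} means 1\% of the median
#'   member length (at least 1).
#' @param threshold conservation threshold (default 1).
#' @param alignment optional pre-computed \code{ProteinMSA} covering
#'   exactly the group's members.
#' @param ... further arguments passed to \code{\link{progressiveMSA}}.
#' @return list with elements \code{rcaa} (stripped \code{EnzymeSet}),
#'   \code{original} (surviving members, intact sequences), \code{map}
#'   (\code{ConservedMap}), \code{alignment} (\code{ProteinMSA}),
#'   \code{lowConservation} (flag), and \code{log} (removals).
#' @export
stripGroup <- function(group, minRcaaLen = 50L, minConserved = NULL,
                       threshold = 1.0, alignment = NULL, ...) {
  stopifnot(is(group, "EnzymeSet"))
  if (length(group) < 2L) stop("singleton group cannot be aligned")
  if (is.null(alignment)) {
    alignment <- progressiveMSA(group, ...)
  } else {
    stopifnot(is(alignment, "ProteinMSA"))
    if (!setequal(seqIds(alignment), seqIds(group)))
      stop("alignment rows do not match group members")
    stripped <- degapRows(alignment)[seqIds(group)]
    if (!identical(unname(stripped),
                   unname(as.character(sequences(group)))))
      stop("alignment rows do not degap to the group's sequences")
  }
  map <- findConservedColumns(alignment, threshold = threshold)
  if (is.null(minConserved))
    minConserved <- max(1L, floor(0.01 * stats::median(
      Biostrings::width(sequences(group)))))
  lowConservation <- length(conservedColumns(map)) < minConserved

  ids <- seqIds(group)
  seqs <- stats::setNames(as.character(sequences(group)), ids)
  rcaaSeqs <- vapply(ids, function(id) {
    stripConserved(seqs[[id]], conservedPositions(map)[[id]])
  }, "")
  keep <- nchar(rcaaSeqs) >= minRcaaLen
  log <- data.frame(id = ids[!keep],
                    group = rep(setName(group), sum(!keep)),
                    reason = rep("short-after-stripping", sum(!keep)),
                    stringsAsFactors = FALSE)
  original <- group[which(keep)]
  rcaa <- if (any(keep)) {
    EnzymeSet(rcaaSeqs[keep], ec = unname(ecNumbers(original)),
              topt = unname(toptValues(original)),
              name = paste0(setName(group), "_rcaa"))
  } else {
    EnzymeSet(character(0), name = paste0(setName(group), "_rcaa"))
  }
  list(rcaa = rcaa, original = original, map = map, alignment = alignment,
       lowConservation = lowConservation, log = log)
}

#' Export a conservation map as tabular text
#'
#' Writes two TSV files: the conserved columns with their residues, and a
#' BED-like per-sequence table of stripped positions (0-based, half-open).
#'
#' @param map a \code{ConservedMap}.
#' @param columnsPath,positionsPath output paths (either may be NULL to
#'   skip).
#' @return invisibly, a list of the data frames written.
#' @export
writeConservedMap <- function(map, columnsPath = NULL, positionsPath = NULL) {
  colsDf <- data.frame(column = conservedColumns(map),
                       residue = map@residues, stringsAsFactors = FALSE)
  pos <- conservedPositions(map)
  posDf <- data.frame(
    id = rep(names(pos), lengths(pos)),
    start = unlist(pos, use.names = FALSE),
    end = unlist(pos, use.names = FALSE) + 1L,
    stringsAsFactors = FALSE)
  if (!is.null(columnsPath))
    utils::write.table(colsDf, columnsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(positionsPath))
    utils::write.table(posDf, positionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(columns = colsDf, positions = posDf))
}
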