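#' @include seqdata.R
#' @useDynLib enzTopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a ProteinMSA from gapped rows
#'
#' @param rows named character vector of equal-length aligned rows (gap
#'   character \code{-}), or an \code{AAStringSet}.
#' @return a \code{\linkS4class{ProteinMSA}}.
#' @export
asProteinMSA <- function(rows) {
  if (is.character(rows)) rows <- Biostrings::AAStringSet(toupper(rows))
  new("ProteinMSA", rows = rows)
}

#' @describeIn ProteinMSA-class aligned rows as a named character vector
#' @param x a \code{ProteinMSA}
#' @export
msaRows <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  stats::setNames(as.character(x@rows), names(x@rows))
}

#' @describeIn ProteinMSA-class alignment width (column count)
#' @export
msaWidth <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  unique(Biostrings::width(x@rows))
}

#' @rdname enzyme-accessors
setMethod("seqIds", "ProteinMSA", function(x) names(x@rows))

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d row(s) x %d column(s)\n",
              length(object@rows), msaWidth(object)))
  invisible(NULL)
})

#' Remove gap characters from alignment rows
#'
#' @param msa a \code{ProteinMSA}.
#' @return named character vector of ungapped sequences.
#' @export
degapRows <- function(msa) {
  rows <- msaRows(msa)
  vapply(rows, function(r) gsub("-", "", r, fixed = TRUE), "")
}

.simpleSubMatrix <- function(match, mismatch) {
  m <- matrix(mismatch, 20L, 20L, dimnames = list(AA_CANONICAL, AA_CANONICAL))
  diag(m) <- match
  m
}

.getSubMatrix <- function(substitutionMatrix) {
  if (is.matrix(substitutionMatrix)) return(substitutionMatrix)
  e <- new.env()
  utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
  get(substitutionMatrix, envir = e)
}

#' Pairwise global (Needleman-Wunsch) alignment with affine gaps
#'
#' Thin wrapper around \code{\link[Biostrings]{pairwiseAlignment}}. Scoring
#' defaults to BLOSUM62 with gap opening 10 and extension 0.5; a simple
#' match/mismatch scheme can be requested instead via \code{match} /
#' \code{mismatch}.
#'
#' @param a,b residue strings (validated; non-empty).
#' @param substitutionMatrix matrix or the name of one shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gapOpening,gapExtension positive gap penalties.
#' @param match,mismatch when \code{match} is given, a uniform
#'   match/mismatch matrix replaces \code{substitutionMatrix}.
#' @return \code{list(alignedA, alignedB, score)}; the aligned strings have
#'   equal length and contain \code{-} for gaps.
#' @examples
#' pairwiseGlobalAlign("ACDE", "ADE", match = 1, mismatch = 0,
#'                     gapOpening = 0, gapExtension = 1)
#' @export
pairwiseGlobalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 0.5,
                                match = NULL, mismatch = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  sub <- if (!is.null(match)) {
    .simpleSubMatrix(match, if (is.null(mismatch)) 0 else mismatch)
  } else {
    .getSubMatrix(substitutionMatrix)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  list(alignedA = as.character(Biostrings::alignedPattern(pa)),
       alignedB = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Percent identity between two sequences
#'
#' Global-alignment percent identity: matches divided by alignment length
#' (including gap columns), times 100.
#'
#' @inheritParams pairwiseGlobalAlign
#' @return a number in [0, 100].
#' @export
percentIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                            gapOpening = 10, gapExtension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .getSubMatrix(substitutionMatrix),
    gapOpening = gapOpening, gapExtension = gapExtension, type = "global")
  Biostrings::pid(pa, type = "PID1")
}

# fractional-common-k-mer distance used for the guide tree (the fast
# alignment-free distance progressive aligners typically use)
.kmerCounts <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(table(seq))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

.kmerDistMatrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, .kmerCounts, k = k)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ci <- counts[[i]]
    for (j in (i + 1L):n) {
      cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      common <- sum(pmin(ci[shared], cj[shared]))
      d[i, j] <- d[j, i] <- 1 - common / min(sum(ci), sum(cj))
    }
  }
  d
}

# 21 x width frequency profile (20 residues + gap) of a set of aligned rows
.profileOf <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, ""))
  width <- ncol(chars)
  prof <- matrix(0, 21L, width)
  lookup <- stats::setNames(seq_len(21L), c(AA_CANONICAL, "-"))
  for (j in seq_len(width)) {
    tab <- tabulate(lookup[chars[, j]], nbins = 21L)
    prof[, j] <- tab / nrow(chars)
  }
  prof
}

# merge two row blocks given a move vector (1 both, 2 A only, 3 B only)
.mergeRows <- function(rowsA, rowsB, moves) {
  takesA <- moves != 3L
  takesB <- moves != 2L
  idxA <- cumsum(takesA)
  idxB <- cumsum(takesB)
  expand <- function(row, takes, idx) {
    chars <- strsplit(row, "")[[1L]]
    out <- rep("-", length(moves))
    out[takes] <- chars[idx[takes]]
    paste(out, collapse = "")
  }
  c(vapply(rowsA, expand, "", takes = takesA, idx = idxA),
    vapply(rowsB, expand, "", takes = takesB, idx = idxB))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by UPGMA on an alignment-free 3-mer distance (or on
#' global-alignment percent identity) and merges sequence profiles along it
#' with an affine-gap profile-profile Needleman-Wunsch step (BLOSUM62
#' expected-score column scoring). Gap-stripping any output row reproduces
#' the corresponding input sequence. An external aligner producing aligned
#' FASTA can be substituted via \code{external}.
#'
#' @param group an \code{EnzymeSet} with at least two members.
#' @param substitutionMatrix substitution matrix name (default BLOSUM62).
#' @param gapOpening,gapExtension positive affine gap penalties (defaults
#'   20 and 0.5). The profile-merge opening penalty is deliberately higher
#'   than the pairwise default of 10: column scores are expected
#'   substitution scores averaged over profile members, which compresses
#'   mismatch magnitudes, and a proportionally larger opening cost is
#'   needed so that spurious gap pairs cannot substitute for accepted
#'   mismatches.
#' @param guideDist \code{"kmer"} (default) or \code{"pid"}.
#' @param external optional external-aligner command template containing
#'   \code{{in}} and \code{{out}} placeholders, e.g.
#'   \code{"mafft --quiet {in} > {out}"}.
#' @return a \code{\linkS4class{ProteinMSA}} with rows in input order.
#' @export
progressiveMSA <- function(group, substitutionMatrix = "BLOSUM62",
                           gapOpening = 20, gapExtension = 0.5,
                           guideDist = c("kmer", "pid"), external = NULL) {
  stopifnot(is(group, "EnzymeSet"))
  if (length(group) < 2L)
    stop("singleton group: multiple alignment needs at least 2 sequences")
  ids <- seqIds(group)
  seqs <- stats::setNames(as.character(sequences(group)), ids)

  if (!is.null(external)) {
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeFastaSet(group, fin)
    cmd <- gsub("{out}", shQuote(fout),
                gsub("{in}", shQuote(fin), external, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0L || !file.exists(fout))
      stop("external aligner failed (exit ", status, "): ", cmd)
    return(readAlignedFasta(fout))
  }

  guideDist <- match.arg(guideDist)
  # guide-tree tie-breaks are fixed by processing records in id order
  ord <- order(ids)
  ids_s <- ids[ord]
  seqs_s <- seqs[ord]
  n <- length(seqs_s)
  d <- if (guideDist == "kmer") {
    .kmerDistMatrix(seqs_s)
  } else {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- 100 - percentIdentity(seqs_s[i], seqs_s[j],
                                                  substitutionMatrix,
                                                  gapOpening, gapExtension)
    m
  }
  dimnames(d) <- list(ids_s, ids_s)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  sub <- .getSubMatrix(substitutionMatrix)[AA_CANONICAL, AA_CANONICAL]

  blocks <- vector("list", n - 1L)  # row blocks per internal node
  blockOf <- function(k) {
    if (k < 0) stats::setNames(seqs_s[-k], ids_s[-k]) else blocks[[k]]
  }
  for (step in seq_len(n - 1L)) {
    rowsA <- blockOf(tree$merge[step, 1L])
    rowsB <- blockOf(tree$merge[step, 2L])
    moves <- .profileAlignCpp(.profileOf(rowsA), .profileOf(rowsB), sub,
                              gapOpening, gapExtension)
    blocks[[step]] <- .mergeRows(rowsA, rowsB, moves)
  }
  final <- blocks[[n - 1L]]
  asProteinMSA(final[ids])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA with \code{-} gaps.
#' @return a \code{\linkS4class{ProteinMSA}}.
#' @export
readAlignedFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty aligned FASTA: ", path)
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  asProteinMSA(stats::setNames(toupper(as.character(set)), names(set)))
}
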