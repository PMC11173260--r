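#' @include seqdata.R
NULL

# Average (isotope-abundance-weighted) residue masses in Daltons, ExPASy
# convention; a free peptide adds one water.
.AA_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
.WATER_MASS <- 18.0153

# Conjoint-triad residue classes (dipole/volume clustering, 7 classes)
.CT_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C"))

# Three-group residue tables for the seven physicochemical attributes used
# by the composition/transition/distribution descriptor family.
.CTD_GROUPS <- list(
  hydrophobicity = list("RKEDQN", "GASTPHY", "CLVIMFW"),
  vdwvolume      = list("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity       = list("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability = list("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge         = list("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct = list("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess  = list("ALFCGIVW", "RKQEND", "MSPTHY"))

.seqChars <- function(seq) {
  validateResidues(seq)
  strsplit(seq, "")[[1L]]
}

#' Amino acid frequency (20 dimensions)
#'
#' Component t is count(t)/N over the canonical residues in alphabetical
#' order; the vector sums to 1.
#'
#' @param seq a validated, non-empty residue string.
#' @return named numeric vector of length 20.
#' @examples
#' aaFrequency("GGGC")["G"]  # 0.75
#' @export
aaFrequency <- function(seq) {
  chars <- .seqChars(seq)
  counts <- table(factor(chars, levels = AA_CANONICAL))
  stats::setNames(as.numeric(counts) / length(chars), AA_CANONICAL)
}

#' Dipeptide frequency (400 dimensions)
#'
#' Component rs is the count of adjacent pair rs divided by N - 1, in
#' row-major order over (r, s) alphabetical; the vector sums to 1.
#'
#' @param seq residue string of length at least 2.
#' @return named numeric vector of length 400 (names like \code{"AC"}).
#' @export
dipeptideFrequency <- function(seq) {
  chars <- .seqChars(seq)
  n <- length(chars)
  if (n < 2L) stop("dipeptide frequency needs a sequence of length >= 2")
  pairNames <- as.vector(t(outer(AA_CANONICAL, AA_CANONICAL, paste0)))
  pairs <- paste0(chars[-n], chars[-1L])
  counts <- table(factor(pairs, levels = pairNames))
  stats::setNames(as.numeric(counts) / (n - 1L), pairNames)
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da); unmodified
#' termini.
#'
#' @param seq a validated, non-empty residue string.
#' @return mass in Daltons.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(seq) {
  chars <- .seqChars(seq)
  sum(.AA_MASS[chars]) + .WATER_MASS
}

#' Conjoint triad feature (343 dimensions)
#'
#' Residues are mapped into 7 physicochemical classes and all 7^3 class
#' triples are counted over the N - 2 sliding windows. By default the
#' counts are scaled to (count - min) / max (the conventional conjoint-
#' triad normalisation); when every count is zero (impossible for a valid
#' sequence) raw zeros would be returned.
#'
#' @param seq residue string of length at least 3.
#' @param raw return raw window counts instead of normalised values.
#' @return named numeric vector of length 343 (names like \code{"CT.1.2.3"}
#'   in class-index-major order).
#' @export
conjointTriad <- function(seq, raw = FALSE) {
  chars <- .seqChars(seq)
  n <- length(chars)
  if (n < 3L) stop("conjoint triad needs a sequence of length >= 3")
  classOf <- integer(20L)
  names(classOf) <- AA_CANONICAL
  for (k in seq_along(.CT_CLASSES)) classOf[.CT_CLASSES[[k]]] <- k
  cls <- classOf[chars]
  triadIdx <- (cls[1:(n - 2L)] - 1L) * 49L + (cls[2:(n - 1L)] - 1L) * 7L +
    cls[3:n]
  counts <- tabulate(triadIdx, nbins = 343L)
  labels <- sprintf("CT.%d.%d.%d",
                    rep(1:7, each = 49L),
                    rep(rep(1:7, each = 7L), times = 7L),
                    rep(1:7, times = 49L))
  if (raw) return(stats::setNames(as.numeric(counts), labels))
  if (max(counts) > 0L) {
    v <- (counts - min(counts)) / max(counts)
  } else {
    v <- as.numeric(counts)
  }
  stats::setNames(v, labels)
}

# positions (1-based) at which occurrence number ceil(q * n) of a group is
# reached, expressed as a percentage of sequence length
.distributionBlock <- function(member, n) {
  hits <- which(member)
  cnt <- length(hits)
  if (cnt == 0L) return(rep(0, 5L))
  qIdx <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * cnt))
  hits[qIdx] / n * 100
}

#' Distribution descriptor, CTDD (105 dimensions)
#'
#' For each of 7 physicochemical attributes, residues are labeled into the
#' attribute's 3 groups; for each group the sequence positions (1-based,
#' as a percentage of sequence length) at which the first occurrence and
#' 25\%, 50\%, 75\% and 100\% of the group's occurrences are reached
#' (count thresholds rounded up) are reported. Absent groups yield five
#' zeros. Total 7 x 3 x 5 = 105 values, attribute-major.
#'
#' @param seq a validated, non-empty residue string.
#' @return named numeric vector of length 105, all values in [0, 100].
#' @export
ctdd <- function(seq) {
  chars <- .seqChars(seq)
  n <- length(chars)
  out <- numeric(0)
  nm <- character(0)
  for (attr in names(.CTD_GROUPS)) {
    groups <- .CTD_GROUPS[[attr]]
    for (g in seq_along(groups)) {
      member <- chars %in% strsplit(groups[[g]], "")[[1L]]
      out <- c(out, .distributionBlock(member, n))
      nm <- c(nm, sprintf("CTDD.%s.G%d.%s", attr, g,
                          c("first", "p25", "p50", "p75", "p100")))
    }
  }
  stats::setNames(out, nm)
}

# block layout of the 12 standard descriptor combinations, in the order
# the blocks are concatenated
.COMBO_BLOCKS <- list(
  c("AA"),
  c("DP"),
  c("AA", "DP"),
  c("AA", "CTF", "CTDD"),
  c("DP", "CTF", "CTDD"),
  c("AA", "DP", "CTF", "CTDD"),
  c("AA", "MW"),
  c("DP", "MW"),
  c("AA", "DP", "MW"),
  c("AA", "MW", "CTF", "CTDD"),
  c("DP", "MW", "CTF", "CTDD"),
  c("AA", "DP", "MW", "CTF", "CTDD"))

.BLOCK_FUN <- list(
  AA = function(seq) aaFrequency(seq),
  DP = function(seq) dipeptideFrequency(seq),
  MW = function(seq) c(MW = molecularWeight(seq)),
  CTF = function(seq) conjointTriad(seq),
  CTDD = function(seq) ctdd(seq))

#' Dimensions of the 12 standard descriptor combinations
#'
#' @return integer vector of length 12.
#' @export
comboDimensions <- function() {
  dims <- c(AA = 20L, DP = 400L, MW = 1L, CTF = 343L, CTDD = 105L)
  vapply(.COMBO_BLOCKS, function(b) sum(dims[b]), 0L)
}

#' Build a descriptor matrix for a dataset
#'
#' Computes one of the 12 standard descriptor combinations for every record
#' and stacks them into a \code{\linkS4class{FeatureMatrix}} (rows in
#' record order, columns concatenated block-wise in the combination's
#' listed order).
#'
#' @param dataset an \code{EnzymeSet}.
#' @param comboId integer 1-12.
#' @return an unstandardized \code{FeatureMatrix}.
#' @examples
#' es <- EnzymeSet(c(a = "ACDEFGHIKL", b = "ACDEFGHIKM"))
#' ncol(featureValues(buildFeatureMatrix(es, 7)))  # 21
#' @export
buildFeatureMatrix <- function(dataset, comboId) {
  stopifnot(is(dataset, "EnzymeSet"))
  comboId <- as.integer(comboId)
  if (is.na(comboId) || comboId < 1L || comboId > 12L)
    stop("comboId must be an integer in 1..12")
  blocks <- .COMBO_BLOCKS[[comboId]]
  ids <- seqIds(dataset)
  seqs <- stats::setNames(as.character(sequences(dataset)), ids)
  minLenOf <- c(AA = 1L, DP = 2L, MW = 1L, CTF = 3L, CTDD = 1L)
  rows <- lapply(ids, function(id) {
    unlist(lapply(blocks, function(b) {
      if (nchar(seqs[[id]]) < minLenOf[[b]])
        stop(sprintf("record '%s' too short for descriptor %s", id, b))
      .BLOCK_FUN[[b]](seqs[[id]])
    }))
  })
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  new("FeatureMatrix", values = values, comboId = comboId,
      standardized = FALSE, center = numeric(0), scale = numeric(0))
}

#' @rdname FeatureMatrix-class
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d record(s) x %d descriptor(s) (combo %s%s)\n",
              nrow(object@values), ncol(object@values),
              ifelse(is.na(object@comboId), "-", object@comboId),
              if (object@standardized) ", standardized" else ""))
  invisible(NULL)
})

#' Standardize feature matrices with training-set statistics
#'
#' Per-column z-scoring with mean and standard deviation estimated on the
#' training matrix only and applied to all matrices (leakage-free).
#' Zero-variance columns pass through centred but unscaled (SD treated
#' as 1). Already-standardized inputs are refused.
#'
#' @param train an unstandardized \code{FeatureMatrix}.
#' @param others optional list of \code{FeatureMatrix} sharing the combo.
#' @return \code{list(train, others, scaler)} where \code{scaler} carries
#'   \code{center} and \code{scale}.
#' @export
standardizeFeatures <- function(train, others = list()) {
  stopifnot(is(train, "FeatureMatrix"))
  if (train@standardized) stop("training matrix is already standardized")
  center <- colMeans(train@values)
  scale <- apply(train@values, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  applyScaler <- function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    if (fm@standardized) stop("matrix is already standardized")
    if (ncol(fm@values) != length(center))
      stop("dimension mismatch between matrices")
    v <- sweep(sweep(fm@values, 2L, center, "-"), 2L, scale, "/")
    new("FeatureMatrix", values = v, comboId = fm@comboId,
        standardized = TRUE, center = center, scale = scale)
  }
  list(train = applyScaler(train), others = lapply(others, applyScaler),
       scaler = list(center = center, scale = scale))
}

#' Write / read a feature matrix as TSV
#'
#' Header row of descriptor names with the record id in the first column.
#'
#' @param fm a \code{FeatureMatrix}.
#' @param path file path.
#' @return \code{path} (write) or a \code{FeatureMatrix} (read).
#' @export
writeFeatureMatrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm@values), fm@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param comboId combination id to record on the restored object.
#' @export
readFeatureMatrix <- function(path, comboId = NA_integer_) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  new("FeatureMatrix", values = values, comboId = as.integer(comboId),
      standardized = FALSE, center = numeric(0), scale = numeric(0))
}
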