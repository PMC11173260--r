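#' @import methods
#' @importFrom Biostrings AAStringSet width
NULL

#' The 20 canonical amino-acid one-letter codes, alphabetically ordered
#'
#' All descriptor layouts in the package (amino-acid frequencies, dipeptide
#' frequencies, conjoint triads) index residues in this fixed order.
#'
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' EnzymeSet: a labeled collection of enzyme sequences
#'
#' An \code{EnzymeSet} holds one or more protein sequences together with the
#' per-record annotation the pipeline needs: an optional EC number (four
#' dot-separated fields) and an optional experimentally determined optimal
#' catalytic temperature (Topt, in degrees Celsius). Sequences are stored as
#' a \link[Biostrings]{AAStringSet} whose names are the record identifiers.
#'
#' Validity rules: identifiers are unique and non-empty; every sequence is
#' non-empty and uses only the 20 canonical residue letters; Topt values,
#' when present, lie strictly between 0 and 120 degrees C.
#'
#' @slot sequences \code{AAStringSet}; names are record ids.
#' @slot ec character vector of EC numbers (\code{NA} when unknown).
#' @slot topt numeric vector of Topt labels in degrees C (\code{NA} when
#'   unknown).
#' @slot name a label for the collection (e.g. a dataset or EC-group name).
#'
#' @seealso \code{\link{EnzymeSet}} (constructor), \code{\link{readFastaSet}},
#'   \code{\link{readDatasetTable}}, \code{\link{groupByEC}}
#' @name EnzymeSet-class
#' @rdname EnzymeSet-class
#' @exportClass EnzymeSet
setClass("EnzymeSet",
  slots = c(
    sequences = "AAStringSet",
    ec = "character",
    topt = "numeric",
    name = "character"
  )
)

setValidity("EnzymeSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  msg <- character(0)
  if (is.null(ids) && n > 0L)
    msg <- c(msg, "sequences must be named by record id")
  if (!is.null(ids)) {
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate record ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(!nzchar(ids)))
      msg <- c(msg, "empty record id")
  }
  if (length(object@ec) != n || length(object@topt) != n)
    msg <- c(msg, "ec and topt must be parallel to sequences")
  if (n > 0L) {
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "empty sequence(s) present")
    bad <- .nonCanonicalIds(object@sequences)
    if (length(bad))
      msg <- c(msg, sprintf("non-canonical residues in: %s",
                            paste(bad, collapse = ", ")))
    t_ok <- is.na(object@topt) | (object@topt > 0 & object@topt < 120)
    if (!all(t_ok))
      msg <- c(msg, sprintf("Topt outside (0, 120) for: %s",
                            paste(ids[!t_ok], collapse = ", ")))
  }
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

# ids of sequences containing anything outside the canonical 20 letters
.nonCanonicalIds <- function(aaset) {
  freq <- Biostrings::letterFrequency(aaset, letters = AA_CANONICAL)
  ids <- names(aaset)
  ids[rowSums(freq) != Biostrings::width(aaset)]
}

#' ProteinMSA: a multiple sequence alignment of protein sequences
#'
#' Equal-width gapped rows over the canonical alphabet plus the gap
#' character \code{-}. Removing the gaps from each row reproduces the input
#' sequence of the corresponding record.
#'
#' @slot rows \code{AAStringSet} of aligned rows (may contain \code{-});
#'   names are record ids.
#'
#' @seealso \code{\link{progressiveMSA}}, \code{\link{findConservedColumns}}
#' @name ProteinMSA-class
#' @rdname ProteinMSA-class
#' @exportClass ProteinMSA
setClass("ProteinMSA", slots = c(rows = "AAStringSet"))

setValidity("ProteinMSA", function(object) {
  n <- length(object@rows)
  msg <- character(0)
  if (n < 1L)
    msg <- c(msg, "alignment must contain at least one row")
  w <- Biostrings::width(object@rows)
  if (n > 0L && length(unique(w)) != 1L)
    msg <- c(msg, "aligned rows differ in width")
  ids <- names(object@rows)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "rows must carry unique record ids")
  if (length(msg)) msg else TRUE
})

#' ConservedMap: conserved alignment columns and their sequence positions
#'
#' Produced by \code{\link{findConservedColumns}}. Column indices and
#' per-sequence residue positions are 0-based; position sets are the
#' ungapped indices, in each original sequence, of the residues sitting in
#' the conserved columns.
#'
#' @slot columns sorted integer vector of conserved column indices (0-based).
#' @slot residues character vector parallel to \code{columns}: the residue
#'   occupying each conserved column.
#' @slot positions named list (one element per alignment row) of sorted
#'   0-based ungapped residue indices.
#' @slot width total column count of the source alignment.
#' @slot threshold the conservation threshold the map was computed at.
#'
#' @name ConservedMap-class
#' @rdname ConservedMap-class
#' @exportClass ConservedMap
setClass("ConservedMap",
  slots = c(
    columns = "integer",
    residues = "character",
    positions = "list",
    width = "integer",
    threshold = "numeric"
  )
)

setValidity("ConservedMap", function(object) {
  msg <- character(0)
  if (length(object@columns) != length(object@residues))
    msg <- c(msg, "columns and residues must be parallel")
  if (is.unsorted(object@columns, strictly = TRUE))
    msg <- c(msg, "columns must be strictly increasing")
  if (length(object@columns) &&
      (min(object@columns) < 0L || max(object@columns) >= object@width))
    msg <- c(msg, "column index outside [0, width)")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: a descriptor matrix over a set of records
#'
#' Rows are records (rownames = ids), columns a named descriptor block or
#' one of the 12 standard descriptor combinations. When standardized, the
#' per-column training mean and standard deviation used are retained so the
#' same scaling can be applied to query features.
#'
#' @slot values numeric matrix, no missing values.
#' @slot comboId integer in 1..12, or NA for a single-family block.
#' @slot standardized logical flag.
#' @slot center,scale per-column scaler statistics (length 0 until
#'   standardized).
#'
#' @seealso \code{\link{buildFeatureMatrix}}, \code{\link{standardizeFeatures}}
#' @name FeatureMatrix-class
#' @rdname FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(
    values = "matrix",
    comboId = "integer",
    standardized = "logical",
    center = "numeric",
    scale = "numeric"
  ),
  prototype = prototype(comboId = NA_integer_, standardized = FALSE,
                        center = numeric(0), scale = numeric(0))
)

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "feature matrix contains missing or non-finite values")
  if (is.null(rownames(object@values)) && nrow(object@values) > 0L)
    msg <- c(msg, "feature matrix rows must be named by record id")
  if (object@standardized &&
      (length(object@center) != ncol(object@values) ||
       length(object@scale) != ncol(object@values)))
    msg <- c(msg, "scaler statistics must match column count")
  if (length(msg)) msg else TRUE
})

#' ToptBundle: a trained end-to-end Topt predictor
#'
#' Everything needed to process a novel sequence exactly as the training
#' data were processed: the per-EC-group reference alignments and conserved
#' maps, the fitted scaler, the standardized training features and labels,
#' the fitted regressor, and a manifest of configuration and seeds.
#'
#' @slot comboId descriptor combination the bundle was trained with.
#' @slot spec the model specification (see \code{\link{modelSpec}}).
#' @slot model the fitted regressor object.
#' @slot scaler list with \code{center} and \code{scale}.
#' @slot trainX standardized training feature matrix.
#' @slot trainY training Topt labels (degrees C).
#' @slot groups named list (by EC group label) of
#'   \code{list(alignment = ProteinMSA, map = ConservedMap)}.
#' @slot originals full-sequence \code{EnzymeSet} retained for EC
#'   assignment by nearest homologue.
#' @slot rcaa conserved-residue-stripped \code{EnzymeSet} the model was
#'   trained on (full-sequence mode stores the originals here too).
#' @slot mode \code{"rcaa"} or \code{"full"}.
#' @slot manifest list of configuration, seed and digest information.
#'
#' @seealso \code{\link{trainBundle}}, \code{\link{predictTopt}}
#' @name ToptBundle-class
#' @rdname ToptBundle-class
#' @exportClass ToptBundle
setClass("ToptBundle",
  slots = c(
    comboId = "integer",
    spec = "list",
    model = "ANY",
    scaler = "list",
    trainX = "matrix",
    trainY = "numeric",
    groups = "list",
    originals = "EnzymeSet",
    rcaa = "EnzymeSet",
    mode = "character",
    manifest = "list"
  )
)

setValidity("ToptBundle", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("full", "rcaa"))
    msg <- c(msg, "mode must be 'full' or 'rcaa'")
  if (!is.na(object@comboId) && !(object@comboId %in% 1:12))
    msg <- c(msg, "comboId must be in 1..12")
  if (nrow(object@trainX) != length(object@trainY))
    msg <- c(msg, "trainX and trainY disagree in length")
  if (length(msg)) msg else TRUE
})
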