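#' @include AllClasses.R
NULL

#' Accessors for EnzymeSet and friends
#'
#' \code{seqIds} returns record identifiers; \code{sequences} the underlying
#' \code{AAStringSet}; \code{ecNumbers} the EC annotation; \code{toptValues}
#' the Topt labels in degrees C; \code{setName} the collection label.
#'
#' @param x an \code{\linkS4class{EnzymeSet}} (or \code{ProteinMSA} for
#'   \code{seqIds}).
#' @return vectors parallel to the records of \code{x}.
#' @name enzyme-accessors
#' @rdname enzyme-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname enzyme-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname enzyme-accessors
#' @export
setGeneric("ecNumbers", function(x) standardGeneric("ecNumbers"))

#' @rdname enzyme-accessors
#' @export
setGeneric("toptValues", function(x) standardGeneric("toptValues"))

#' @rdname enzyme-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname ConservedMap-class
#' @param x a \code{ConservedMap}.
#' @export
setGeneric("conservedColumns", function(x) standardGeneric("conservedColumns"))

#' @rdname ConservedMap-class
#' @export
setGeneric("conservedResidues", function(x) standardGeneric("conservedResidues"))

#' @rdname ConservedMap-class
#' @export
setGeneric("conservedPositions", function(x) standardGeneric("conservedPositions"))

#' @rdname FeatureMatrix-class
#' @param x a \code{FeatureMatrix}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
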