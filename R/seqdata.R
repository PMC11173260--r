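#' @include AllGenerics.R
NULL

#' Construct an EnzymeSet
#'
#' @param seqs named character vector or \code{AAStringSet} of protein
#'   sequences (names are record ids). Sequences are uppercased.
#' @param ec optional character vector of EC numbers (recycled \code{NA}).
#' @param topt optional numeric vector of Topt labels in degrees C.
#' @param name label for the collection.
#'
#' @return a validated \code{\linkS4class{EnzymeSet}}.
#' @examples
#' es <- EnzymeSet(c(P1 = "ACDE", P2 = "ACDF"), ec = c("3.1.3.8", "3.1.3.8"),
#'                 topt = c(55, 60))
#' seqIds(es)
#' @export
EnzymeSet <- function(seqs, ec = NULL, topt = NULL, name = "dataset") {
  if (is.character(seqs)) {
    seqs <- Biostrings::AAStringSet(toupper(seqs))
  } else if (is(seqs, "AAStringSet")) {
    seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  } else {
    stop("seqs must be a named character vector or an AAStringSet")
  }
  n <- length(seqs)
  if (is.null(ec)) ec <- rep(NA_character_, n)
  if (is.null(topt)) topt <- rep(NA_real_, n)
  new("EnzymeSet", sequences = seqs, ec = as.character(ec),
      topt = as.numeric(topt), name = name)
}

#' @rdname enzyme-accessors
setMethod("seqIds", "EnzymeSet", function(x) names(x@sequences))

#' @rdname enzyme-accessors
setMethod("sequences", "EnzymeSet", function(x) x@sequences)

#' @rdname enzyme-accessors
setMethod("ecNumbers", "EnzymeSet", function(x) {
  stats::setNames(x@ec, names(x@sequences))
})

#' @rdname enzyme-accessors
setMethod("toptValues", "EnzymeSet", function(x) {
  stats::setNames(x@topt, names(x@sequences))
})

#' @rdname enzyme-accessors
setMethod("setName", "EnzymeSet", function(x) x@name)

#' @describeIn EnzymeSet-class number of records
#' @param x an \code{EnzymeSet}
#' @export
setMethod("length", "EnzymeSet", function(x) length(x@sequences))

#' @describeIn EnzymeSet-class subset by index, id or logical mask
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "EnzymeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (anyNA(i)) stop("unknown record id in subset")
  new("EnzymeSet", sequences = x@sequences[i], ec = x@ec[i],
      topt = x@topt[i], name = x@name)
})

setMethod("show", "EnzymeSet", function(object) {
  cat(sprintf("EnzymeSet '%s' with %d record(s)\n", object@name,
              length(object)))
  if (length(object)) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  sequence length: %d-%d\n", min(w), max(w)))
    cat(sprintf("  EC annotated: %d | Topt labeled: %d\n",
                sum(!is.na(object@ec)), sum(!is.na(object@topt))))
  }
  invisible(NULL)
})

#' Read a FASTA file into an EnzymeSet
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased and validated against the canonical alphabet.
#'
#' @param path path to a (plain-text) FASTA file.
#' @param name label for the resulting set.
#' @return an \code{\linkS4class{EnzymeSet}} without EC/Topt annotation.
#' @export
readFastaSet <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  EnzymeSet(stats::setNames(toupper(as.character(set)), names(set)),
            name = name)
}

#' Write an EnzymeSet (or alignment rows) to FASTA
#'
#' @param x an \code{EnzymeSet} or \code{ProteinMSA}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSet <- function(x, path) {
  set <- if (is(x, "ProteinMSA")) x@rows else sequences(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a labeled dataset table
#'
#' Reads a delimited text table with header columns \code{id}, \code{ec},
#' \code{topt}, \code{seq} (comma or tab delimited; the delimiter is
#' sniffed from the header line). Empty strings and \code{NA} in \code{ec}
#' or \code{topt} are treated as missing.
#'
#' @param path path to the table.
#' @param name label for the resulting set.
#' @return an \code{\linkS4class{EnzymeSet}}.
#' @export
readDatasetTable <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("id", "ec", "topt", "seq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("dataset table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  topt_raw <- trimws(df$topt)
  topt <- suppressWarnings(as.numeric(topt_raw))
  bad <- which(!is.na(topt_raw) & nzchar(topt_raw) &
               topt_raw != "NA" & is.na(topt))
  if (length(bad))
    stop(sprintf("unparseable topt at data row %d: '%s'",
                 bad[1L], topt_raw[bad[1L]]))
  ec <- trimws(df$ec)
  ec[!nzchar(ec) | ec == "NA"] <- NA_character_
  EnzymeSet(stats::setNames(toupper(trimws(df$seq)), trimws(df$id)),
            ec = ec, topt = topt, name = name)
}

#' Write an EnzymeSet to a dataset table
#'
#' @param x an \code{EnzymeSet}.
#' @param path output path; extension \code{.tsv} selects tab delimiters,
#'   anything else commas.
#' @return \code{path}, invisibly.
#' @export
writeDatasetTable <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(id = seqIds(x), ec = ecNumbers(x), topt = toptValues(x),
                   seq = as.character(sequences(x)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a residue string against the canonical alphabet
#'
#' Returns its input unchanged when the sequence is non-empty and uses only
#' the 20 canonical letters; otherwise raises an error listing the
#' offending characters and their 0-based positions. Ambiguity codes
#' (B, J, O, U, X, Z) and gaps are rejected, not repaired.
#'
#' @param seq a single residue string.
#' @return \code{seq}, invisibly-checked.
#' @examples
#' validateResidues("ACDEFGHIKLMNPQRSTVWY")
#' @export
validateResidues <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!chars %in% AA_CANONICAL)
  if (length(bad))
    stop(sprintf("non-canonical residue(s): %s",
                 paste(sprintf("'%s' at position %d", chars[bad], bad - 1L),
                       collapse = ", ")))
  seq
}

#' Partition an EnzymeSet by EC number
#'
#' Records are partitioned by their full four-field EC string (i.e. by the
#' fourth digit within a shared class such as EC 3.1.3.X). Groups are
#' returned in lexicographic EC order.
#'
#' @param x an \code{EnzymeSet}; every record must carry an EC number.
#' @return named list of \code{EnzymeSet}, one per EC group.
#' @export
groupByEC <- function(x) {
  stopifnot(is(x, "EnzymeSet"))
  if (length(x) == 0L) return(stats::setNames(list(), character(0)))
  ec <- ecNumbers(x)
  if (anyNA(ec))
    stop("record(s) lacking an EC number: ",
         paste(seqIds(x)[is.na(ec)], collapse = ", "))
  keys <- sort(unique(ec))
  out <- lapply(keys, function(k) {
    g <- x[which(ec == k)]
    g@name <- k
    g
  })
  stats::setNames(out, keys)
}

#' Apply baseline dataset filters to EC groups
#'
#' Drops records whose sequence is shorter than \code{minLen}, then drops
#' groups reduced to a single member (a singleton cannot be multiply
#' aligned). Every removal is logged with its reason.
#'
#' @param groups named list of \code{EnzymeSet} as from
#'   \code{\link{groupByEC}}.
#' @param minLen minimum sequence length retained (default 50).
#' @return \code{list(groups = filtered list, log = data.frame(id, group,
#'   reason))}; reasons are \code{"short-sequence"} and
#'   \code{"singleton-group"}.
#' @export
applyBaselineFilters <- function(groups, minLen = 50L) {
  log <- data.frame(id = character(0), group = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  out <- list()
  for (key in names(groups)) {
    g <- groups[[key]]
    short <- Biostrings::width(sequences(g)) < minLen
    if (any(short)) {
      log <- rbind(log, data.frame(id = seqIds(g)[short], group = key,
                                   reason = "short-sequence",
                                   stringsAsFactors = FALSE))
      g <- g[!short]
    }
    if (length(g) == 1L) {
      log <- rbind(log, data.frame(id = seqIds(g), group = key,
                                   reason = "singleton-group",
                                   stringsAsFactors = FALSE))
    } else if (length(g) >= 2L) {
      out[[key]] <- g
    }
  }
  list(groups = out, log = log)
}

#' Combine several EnzymeSets into one
#'
#' @param sets list of \code{EnzymeSet} with disjoint record ids.
#' @param name label for the combined set.
#' @return an \code{EnzymeSet}.
#' @export
combineSets <- function(sets, name = "combined") {
  sets <- sets[vapply(sets, length, 0L) > 0L]
  if (!length(sets)) return(EnzymeSet(character(0), name = name))
  EnzymeSet(
    stats::setNames(unlist(lapply(sets, function(s) as.character(sequences(s)))),
                    unlist(lapply(sets, seqIds))),
    ec = unlist(lapply(sets, function(s) unname(ecNumbers(s)))),
    topt = unlist(lapply(sets, function(s) unname(toptValues(s)))),
    name = name
  )
}
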