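#' @include align.R
NULL

#' Pairwise similarity matrix for an enzyme group
#'
#' Global-alignment percent identity (matches / alignment length x 100)
#' between every pair of members; the diagonal is 100.
#'
#' @param group an \code{EnzymeSet} with at least two members.
#' @param ... scoring arguments passed to \code{\link{percentIdentity}}.
#' @return symmetric numeric matrix with id dimnames.
#' @export
pairwiseSimilarityMatrix <- function(group, ...) {
  stopifnot(is(group, "EnzymeSet"))
  if (length(group) < 2L) stop("singleton group has no pairwise similarities")
  ids <- seqIds(group)
  seqs <- stats::setNames(as.character(sequences(group)), ids)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- percentIdentity(seqs[i], seqs[j], ...)
    }
  }
  m
}

#' Build a sequence similarity network
#'
#' Nodes are the group's records; an edge joins two records when their
#' similarity is at least \code{threshold}. No self-edges.
#'
#' @param matrix symmetric similarity matrix with id dimnames.
#' @param threshold minimum similarity for an edge.
#' @return a list of class \code{"SSNGraph"} with elements \code{nodes},
#'   \code{edges} (data.frame id1, id2, score) and \code{threshold}.
#' @export
buildSSN <- function(matrix, threshold) {
  stopifnot(is.matrix(matrix), isSymmetric(unname(matrix)))
  ids <- rownames(matrix)
  pairs <- which(upper.tri(matrix) & matrix >= threshold, arr.ind = TRUE)
  edges <- data.frame(id1 = ids[pairs[, 1L]], id2 = ids[pairs[, 2L]],
                      score = matrix[pairs], stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges, threshold = threshold),
            class = "SSNGraph")
}

#' @export
print.SSNGraph <- function(x, ...) {
  cat(sprintf("SSNGraph: %d node(s), %d edge(s), threshold %g\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Connected components of a similarity network
#'
#' @param graph an \code{SSNGraph} from \code{\link{buildSSN}}.
#' @return list of character vectors of member ids, each sorted, ordered by
#'   their smallest member id.
#' @export
connectedComponents <- function(graph) {
  stopifnot(inherits(graph, "SSNGraph"))
  g <- igraph::graph_from_data_frame(graph$edges[, c("id1", "id2")],
                                     directed = FALSE,
                                     vertices = graph$nodes)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  comps <- unname(comps[order(vapply(comps, `[`, "", 1L))])
  comps
}

#' Drop single-member network clusters
#'
#' @param components list of id sets from \code{\link{connectedComponents}}.
#' @return \code{list(kept, removed)}: the multi-member components and the
#'   ids of the discarded singletons.
#' @export
pruneSingletons <- function(components) {
  singleton <- lengths(components) == 1L
  list(kept = components[!singleton],
       removed = unlist(components[singleton], use.names = FALSE) %||%
         character(0))
}

#' Choose the similarity threshold with the fewest isolated nodes
#'
#' Evaluates each candidate threshold and returns the one whose network has
#' the fewest isolated (degree-zero) nodes; ties are broken toward the
#' higher threshold (tighter clusters).
#'
#' @param matrix symmetric similarity matrix.
#' @param candidates numeric vector of candidate thresholds.
#' @return the selected threshold.
#' @export
chooseThreshold <- function(matrix, candidates) {
  stopifnot(length(candidates) >= 1L)
  isolated <- vapply(candidates, function(th) {
    g <- buildSSN(matrix, th)
    connected <- unique(c(g$edges$id1, g$edges$id2))
    length(setdiff(g$nodes, connected))
  }, 0L)
  best <- candidates[isolated == min(isolated)]
  max(best)
}

#' Sub-group a low-conservation family through its similarity network
#'
#' Convenience wrapper implementing the fallback used when a family aligns
#' with too few conserved columns: compute pairwise similarities, pick the
#' threshold minimising isolated nodes, take connected components as
#' sub-groups and discard singleton clusters.
#'
#' @param group an \code{EnzymeSet}.
#' @param candidates candidate thresholds (percent identity; default
#'   \code{seq(30, 90, by = 10)}).
#' @param ... passed to \code{\link{pairwiseSimilarityMatrix}}.
#' @return \code{list(subgroups, removed, threshold, matrix)} where
#'   \code{subgroups} is a list of \code{EnzymeSet} named
#'   \code{<group>#<i>}, each retaining the parent EC annotation.
#' @export
ssnSubgroups <- function(group, candidates = seq(30, 90, by = 10), ...) {
  m <- pairwiseSimilarityMatrix(group, ...)
  th <- chooseThreshold(m, candidates)
  comps <- pruneSingletons(connectedComponents(buildSSN(m, th)))
  subgroups <- lapply(seq_along(comps$kept), function(i) {
    g <- group[comps$kept[[i]]]
    g@name <- sprintf("%s#%d", setName(group), i)
    g
  })
  names(subgroups) <- vapply(subgroups, setName, "")
  list(subgroups = subgroups, removed = comps$removed, threshold = th,
       matrix = m)
}

#' Export a similarity network
#'
#' Writes the edge list as TSV and, optionally, a GraphML file readable by
#' external network viewers.
#'
#' @param graph an \code{SSNGraph}.
#' @param edgeListPath,graphmlPath output paths (either may be NULL).
#' @return invisibly, the edge data frame.
#' @export
writeSSN <- function(graph, edgeListPath = NULL, graphmlPath = NULL) {
  stopifnot(inherits(graph, "SSNGraph"))
  if (!is.null(edgeListPath))
    utils::write.table(graph$edges, edgeListPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphmlPath)) {
    g <- igraph::graph_from_data_frame(graph$edges[, c("id1", "id2")],
                                       directed = FALSE,
                                       vertices = graph$nodes)
    if (nrow(graph$edges))
      igraph::E(g)$score <- graph$edges$score
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  invisible(graph$edges)
}
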