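#' @import methods
NULL

#' Node-labeled undirected graph
#'
#' The central data object: an undirected graph with one opaque string label
#' per vertex. Vertices are indexed 0..n-1 (the indices used in transaction
#' files and in all reported matches). Edges are stored once as unordered
#' pairs in a two-column integer matrix with `u < v`, rows sorted; self-loops
#' and duplicate edges are rejected.
#'
#' @slot graphId single string identifying the graph.
#' @slot labels character vector, one label per vertex.
#' @slot edges integer matrix with two columns (0-based endpoints, `u < v`).
#'
#' @seealso [labeledGraph()] for construction, [readGspan()] for parsing.
#' @export
setClass("LabeledGraph",
  slots = c(graphId = "character", labels = "character", edges = "matrix"))

setValidity("LabeledGraph", function(object) {
  msg <- character(0)
  if (length(object@graphId) != 1L || is.na(object@graphId))
    msg <- c(msg, "graphId must be a single non-NA string")
  e <- object@edges
  n <- length(object@labels)
  if (!is.integer(e) || ncol(e) != 2L)
    return("edges must be a 2-column integer matrix")
  if (nrow(e) > 0) {
    if (anyNA(e) || any(e < 0L) || any(e >= n))
      msg <- c(msg, "edge endpoint out of vertex range")
    else {
      if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
      if (any(e[, 1L] > e[, 2L]))
        msg <- c(msg, "edges must be stored with u < v")
      if (anyDuplicated(paste(e[, 1L], e[, 2L])))
        msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered database of labeled graphs
#'
#' A list of [LabeledGraph-class] objects with unique `graphId`s; the label
#' alphabet of the database is the union of the member graphs' label sets
#' (see [alphabet()]).
#'
#' @slot graphs list of `LabeledGraph`.
#' @export
setClass("GraphDB", slots = c(graphs = "list"))

setValidity("GraphDB", function(object) {
  if (!all(vapply(object@graphs, is, logical(1), "LabeledGraph")))
    return("all database members must be LabeledGraph objects")
  ids <- vapply(object@graphs, function(g) g@graphId, character(1))
  if (anyDuplicated(ids)) return("graph ids must be unique within a database")
  TRUE
})

#' Two-part path-feature index over a graph database
#'
#' `gi` is the global inverted index: for every path feature (a label
#' sequence of at most `lp` vertices, keyed as the labels joined by spaces)
#' the graphs containing it with their occurrence counts. `li` is the local
#' index: per graph, the start-vertex bitset of every contained feature,
#' packed as a raw vector of `ceiling(n/8)` bytes (bit `v` in byte `v %/% 8`,
#' position `v %% 8`). Features are kept in C-locale lexicographic order,
#' graphs in database order, so serialization is canonical.
#'
#' @slot lp maximum path length in vertices.
#' @slot formatVersion serialization format tag.
#' @slot gi named list: feature key -> named integer vector (graph id -> count).
#' @slot li named list: graph id -> named list (feature key -> raw bitset).
#' @slot graphOrder graph ids in database order.
#' @slot vertexCounts named integer vector of per-graph vertex counts.
#'
#' @seealso [buildIndex()], [saveIndex()], [loadIndex()].
#' @export
setClass("PathIndex",
  slots = c(lp = "integer", formatVersion = "character", gi = "list",
            li = "list", graphOrder = "character", vertexCounts = "integer"))

setValidity("PathIndex", function(object) {
  if (length(object@lp) != 1L || is.na(object@lp) || object@lp < 1L)
    return("lp must be a single integer >= 1")
  if (!identical(sort(names(object@li), method = "radix"),
                 sort(object@graphOrder, method = "radix")))
    return("local index must have exactly one entry per graph")
  TRUE
})

#' Features extracted from a query graph
#'
#' `fq` holds the occurrence counts of the maximal enumerated paths of the
#' query (terminal depth-first occurrences only, so every count is a valid
#' lower bound on the feature's occurrences); `fvq` maps each query vertex to
#' the features with a terminal occurrence starting there.
#'
#' @slot fq named integer vector of feature occurrence counts.
#' @slot fvq list, one character vector of feature keys per query vertex.
#' @slot lp maximum path length used for extraction.
#' @export
setClass("QueryFeatures",
  slots = c(fq = "integer", fvq = "list", lp = "integer"))

#' Result of a filter-and-verify query
#'
#' Records the candidate sets after each filtering step, the verified
#' matches, and the matcher's explored-state counts. Matches map query
#' vertices to target vertices using 0-based indices; `matches[[id]]` is a
#' list of such integer vectors for each reported graph.
#'
#' @slot mode `"first"` (report each matching graph once) or `"all"`
#'   (enumerate every distinct embedding).
#' @slot c1 graph ids surviving occurrence-count pruning.
#' @slot c2 graph ids surviving the locality filter.
#' @slot matches named list over matched graphs; each element a list of
#'   integer match vectors.
#' @slot states named numeric vector of search states explored per verified
#'   candidate.
#' @slot nQueryVertices number of query vertices.
#' @export
setClass("QueryResult",
  slots = c(mode = "character", c1 = "character", c2 = "character",
            matches = "list", states = "numeric",
            nQueryVertices = "integer"))
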