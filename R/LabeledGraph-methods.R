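#' Construct a labeled graph
#'
#' @param labels character vector of vertex labels; vertex `i-1` (0-based)
#'   gets `labels[i]`.
#' @param edges `NULL` for an edgeless graph, or a two-column matrix of
#'   0-based vertex indices (one row per undirected edge, either orientation).
#' @param graphId identifier string.
#' @return a [LabeledGraph-class] object.
#' @examples
#' g <- labeledGraph(c("A", "B", "C"), rbind(c(0, 1), c(1, 2)), "chain")
#' nVertices(g)
#' edgeMatrix(g)
#' @export
labeledGraph <- function(labels, edges = NULL, graphId = "g0") {
  labels <- as.character(labels)
  if (is.null(edges) || length(edges) == 0L) {
    e <- matrix(integer(0), 0L, 2L)
  } else {
    e <- matrix(as.integer(edges), ncol = 2L)
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, c(2L, 1L)]
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  new("LabeledGraph", graphId = as.character(graphId), labels = labels,
      edges = e)
}

#' @rdname LabeledGraph-class
#' @aliases graphId,LabeledGraph-method
setMethod("graphId", "LabeledGraph", function(x) x@graphId)

#' @rdname LabeledGraph-class
setMethod("nVertices", "LabeledGraph", function(x) length(x@labels))

#' @rdname LabeledGraph-class
setMethod("vertexLabels", "LabeledGraph", function(x) x@labels)

#' @rdname LabeledGraph-class
setMethod("edgeMatrix", "LabeledGraph", function(x) x@edges)

#' @rdname LabeledGraph-class
setMethod("numEdges", "LabeledGraph", function(x) nrow(x@edges))

#' @rdname LabeledGraph-class
setMethod("adjacencyList", "LabeledGraph", function(x) {
  n <- length(x@labels)
  adj <- rep(list(integer(0)), n)
  e <- x@edges
  if (nrow(e) > 0) {
    ends <- c(e[, 1L], e[, 2L]) + 1L
    other <- c(e[, 2L], e[, 1L])
    grp <- split(other, factor(ends, levels = seq_len(n)))
    adj <- lapply(grp, function(v) sort.int(v))
  }
  unname(adj)
})

#' @export
setMethod("show", "LabeledGraph", function(object) {
  cat(sprintf("LabeledGraph '%s': %d vertices, %d edges, %d labels\n",
              object@graphId, length(object@labels), nrow(object@edges),
              length(unique(object@labels))))
})

#' Construct a graph database
#'
#' @param graphs list of [LabeledGraph-class] objects (ids must be unique).
#' @return a [GraphDB-class] object.
#' @examples
#' db <- graphDB(list(labeledGraph("A", graphId = "g1")))
#' length(db)
#' @export
graphDB <- function(graphs = list()) new("GraphDB", graphs = graphs)

#' @rdname GraphDB-class
#' @aliases length,GraphDB-method
#' @export
setMethod("length", "GraphDB", function(x) length(x@graphs))

#' @rdname GraphDB-class
setMethod("graphIds", "GraphDB",
  function(x) vapply(x@graphs, graphId, character(1)))

#' @rdname GraphDB-class
setMethod("alphabet", "GraphDB", function(x)
  sort(unique(unlist(lapply(x@graphs, vertexLabels), use.names = FALSE)),
       method = "radix"))

#' @rdname GraphDB-class
#' @param i index (position) or graph id (string).
#' @export
setMethod("[[", "GraphDB", function(x, i) {
  if (is.character(i)) {
    k <- match(i, graphIds(x))
    if (is.na(k)) stop("no graph with id '", i, "' in database")
    i <- k
  }
  x@graphs[[i]]
})

#' @export
setMethod("show", "GraphDB", function(object) {
  ng <- length(object@graphs)
  nv <- vapply(object@graphs, nVertices, integer(1))
  ne <- vapply(object@graphs, numEdges, integer(1))
  cat(sprintf("GraphDB: %d graphs, %d total vertices, %d total edges, %d labels\n",
              ng, sum(nv), sum(ne), length(alphabet(object))))
})
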