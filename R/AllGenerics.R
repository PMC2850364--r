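#' @rdname LabeledGraph-class
#' @param x a `LabeledGraph`, `GraphDB`, `PathIndex` or `QueryResult`.
#' @export
setGeneric("graphId", function(x) standardGeneric("graphId"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))

#' @rdname GraphDB-class
#' @param x object.
#' @export
setGeneric("graphIds", function(x) standardGeneric("graphIds"))

#' @rdname GraphDB-class
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname PathIndex-class
#' @param x object.
#' @export
setGeneric("indexLp", function(x) standardGeneric("indexLp"))

#' @rdname PathIndex-class
#' @export
setGeneric("indexFeatures", function(x) standardGeneric("indexFeatures"))

#' @rdname PathIndex-class
#' @export
setGeneric("globalIndex", function(x) standardGeneric("globalIndex"))

#' @rdname PathIndex-class
#' @export
setGeneric("localIndex", function(x) standardGeneric("localIndex"))

#' @rdname QueryFeatures-class
#' @param x object.
#' @export
setGeneric("fqCounts", function(x) standardGeneric("fqCounts"))

#' @rdname QueryFeatures-class
#' @export
setGeneric("fvqSets", function(x) standardGeneric("fvqSets"))

#' @rdname QueryResult-class
#' @param x object.
#' @export
setGeneric("matchedGraphs", function(x) standardGeneric("matchedGraphs"))

#' @rdname QueryResult-class
#' @export
setGeneric("matchList", function(x) standardGeneric("matchList"))

#' @rdname QueryResult-class
#' @param step which filtering step, 1 or 2.
#' @export
setGeneric("candidates", function(x, step = 2L) standardGeneric("candidates"))

#' @rdname QueryResult-class
#' @export
setGeneric("matcherStates", function(x) standardGeneric("matcherStates"))
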