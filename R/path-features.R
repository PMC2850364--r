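#' Path features
#'
#' A path feature is the ordered sequence of vertex labels spelled by a
#' simple path (all vertices distinct) of at most `lp` vertices. Features
#' are keyed as their labels joined by single spaces (labels are
#' whitespace-free tokens in the transaction format, so the key is
#' unambiguous). An occurrence of a feature is a distinct directed simple
#' vertex sequence spelling it — an undirected path is counted once from
#' each endpoint, consistently for database graphs and queries.
#'
#' @param labels character vector of labels, or a feature key.
#' @param key a feature key string.
#' @return `featureKey()` the key string; `featureLabels()` the label vector.
#' @examples
#' featureKey(c("A", "B", "C"))
#' featureLabels("A B C")
#' @name path-features
NULL

#' @rdname path-features
#' @export
featureKey <- function(labels) paste(labels, collapse = " ")

#' @rdname path-features
#' @export
featureLabels <- function(key) strsplit(key, " ", fixed = TRUE)[[1L]]

checkLp <- function(lp) {
  lp <- as.integer(lp)
  if (length(lp) != 1L || is.na(lp) || lp < 1L)
    stop("lp must be a single integer >= 1")
  lp
}

#' Enumerate the simple paths starting at one vertex
#'
#' Depth-first enumeration of every simple vertex sequence of at most `lp`
#' vertices starting at `v`, reported as spelled label sequences, one row
#' per vertex sequence (so the same feature can appear several times).
#' An occurrence is flagged `terminal` when it cannot be extended — it has
#' reached depth `lp` or a dead end; query feature extraction keeps only
#' terminal occurrences. Neighbors are explored in ascending vertex index.
#'
#' @param g a [LabeledGraph-class].
#' @param v 0-based start vertex.
#' @param lp maximum path length in vertices.
#' @return data.frame with columns `feature` (key string) and `terminal`.
#' @examples
#' tri <- labeledGraph(c("A", "B", "C"),
#'                     rbind(c(0, 1), c(1, 2), c(0, 2)))
#' enumerateStartPaths(tri, 0, 3)
#' @export
enumerateStartPaths <- function(g, v, lp = 4L) {
  stopifnot(is(g, "LabeledGraph"))
  lp <- checkLp(lp)
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 0L || v >= nVertices(g))
    stop("start vertex out of range")
  res <- cpp_start_paths(vertexLabels(g), adjacencyList(g), lp, v)
  data.frame(feature = res$feature, terminal = res$terminal,
             stringsAsFactors = FALSE)
}

#' Occurrence counts of all bounded-length path features of a graph
#'
#' For every path feature of at most `lp` vertices contained in `g`, the
#' number of distinct directed simple vertex sequences spelling it.
#' Single-vertex paths are included (their counts are the label counts).
#'
#' @param g a [LabeledGraph-class].
#' @param lp maximum path length in vertices (default 4).
#' @return named integer vector (feature key -> count), keys in C-locale
#'   lexicographic order.
#' @examples
#' star <- labeledGraph(c("A", "B", "C", "C"),
#'                      rbind(c(0, 1), c(1, 2), c(1, 3)))
#' occurrenceCounts(star, 3)[["A B C"]]  # two occurrences
#' @export
occurrenceCounts <- function(g, lp = 4L) {
  stopifnot(is(g, "LabeledGraph"))
  lp <- checkLp(lp)
  res <- cpp_enumerate_features(vertexLabels(g), adjacencyList(g), lp)
  stats::setNames(res$counts, res$features)
}

#' Start-vertex bitsets of all bounded-length path features of a graph
#'
#' For every contained feature, the set of vertices some occurrence starts
#' from, as a packed bitset over the graph's vertices (see [bitset]).
#' Start sets are prefix-closed: if `f` is a prefix of `f2` then every start
#' of `f2` is a start of `f`.
#'
#' @inheritParams occurrenceCounts
#' @return named list (feature key -> raw bitset).
#' @export
startBitsets <- function(g, lp = 4L) {
  stopifnot(is(g, "LabeledGraph"))
  lp <- checkLp(lp)
  res <- cpp_enumerate_features(vertexLabels(g), adjacencyList(g), lp)
  stats::setNames(res$starts, res$features)
}

#' Extract query features (FQ and FVQ)
#'
#' Enumerates the simple paths of the query depth-first and records only the
#' maximal (terminal) occurrences: paths that are proper prefixes of a longer
#' enumerated path from the same start are discarded. `fq` counts terminal
#' occurrences per feature — a valid lower bound on the feature's occurrence
#' count in the query, which is what occurrence-count pruning needs. `fvq`
#' records, per query vertex, the features with a terminal occurrence
#' starting there; it drives the locality filter.
#'
#' @param q the query, a [LabeledGraph-class].
#' @param lp maximum path length in vertices (default 4).
#' @return a [QueryFeatures-class] object.
#' @examples
#' q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)))
#' fqCounts(queryFeatures(q, 2))
#' @export
queryFeatures <- function(q, lp = 4L) {
  stopifnot(is(q, "LabeledGraph"))
  lp <- checkLp(lp)
  res <- cpp_query_features(vertexLabels(q), adjacencyList(q), lp)
  new("QueryFeatures",
      fq = stats::setNames(res$counts, res$features),
      fvq = res$fvq, lp = lp)
}

#' @rdname QueryFeatures-class
#' @aliases fqCounts,QueryFeatures-method
setMethod("fqCounts", "QueryFeatures", function(x) x@fq)

#' @rdname QueryFeatures-class
setMethod("fvqSets", "QueryFeatures", function(x) x@fvq)

#' @export
setMethod("show", "QueryFeatures", function(object) {
  cat(sprintf("QueryFeatures: %d maximal features over %d vertices (lp = %d)\n",
              length(object@fq), length(object@fvq), object@lp))
})
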