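isConnectedGraph <- function(g) {
  n <- nVertices(g)
  if (n <= 1L) return(TRUE)
  adj <- adjacencyList(g)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[v]] + 1L
    fresh <- nb[!seen[nb]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  all(seen)
}

normalizeCompat <- function(compat, n) {
  lapply(compat, function(cv) {
    if (is.raw(cv)) bitsetIndices(cv) else as.integer(cv)
  })
}

#' Backtracking subgraph matching constrained by a compatibility map
#'
#' A VF2-style search over partial embeddings where the per-vertex semantic
#' test is membership in a precomputed candidate set — either plain label
#' equality ([labelCompatibility()]) or the locality compatibility map from
#' [secondStepFilter()], which shrinks the breadth of the search tree
#' without losing any embedding. Semantics are non-induced: every query edge
#' must map onto a target edge; query non-edges impose no constraint.
#' Matches are distinct injective mappings, so automorphic images are
#' reported separately.
#'
#' By default the next query vertex is chosen dynamically: among unmatched
#' vertices adjacent to the partial match, the one with fewest unused
#' candidates (ties by lowest index); target candidates are tried in
#' ascending index, making enumeration deterministic. A fixed `vertexOrder`
#' can be supplied instead, e.g. to compare explored-state counts between
#' two compatibility maps under an identical search order.
#'
#' @param q connected query [LabeledGraph-class] (disconnected queries are
#'   rejected).
#' @param g target [LabeledGraph-class].
#' @param compat list with one element per query vertex: a raw bitset or a
#'   0-based integer vector of admissible target vertices.
#' @param mode `"all"` to enumerate every embedding, `"first"` to stop at
#'   the first.
#' @param maxMatches cap on the number of enumerated matches (`Inf` for no
#'   cap).
#' @param vertexOrder optional 0-based permutation of the query vertices
#'   fixing the assignment order.
#' @return list with `matches` (list of 0-based integer vectors mapping
#'   query vertex `i-1` to `matches[[k]][i]`) and `states` (number of
#'   feasible assignments explored).
#' @examples
#' q <- labeledGraph(c("A", "A", "A"), rbind(c(0, 1), c(1, 2), c(0, 2)))
#' g <- labeledGraph(rep("A", 4), t(combn(0:3, 2)))
#' length(matchCandidate(q, g, labelCompatibility(q, g))$matches)  # 24
#' @export
matchCandidate <- function(q, g, compat, mode = c("all", "first"),
                           maxMatches = Inf, vertexOrder = NULL) {
  stopifnot(is(q, "LabeledGraph"), is(g, "LabeledGraph"))
  mode <- match.arg(mode)
  if (!isConnectedGraph(q))
    stop("disconnected query graphs are not supported")
  nq <- nVertices(q)
  if (length(compat) != nq)
    stop("compatibility map must have one entry per query vertex")
  if (nq == 0L)
    return(list(matches = list(integer(0)), states = 0))
  cand <- normalizeCompat(compat, nVertices(g))
  ord <- if (is.null(vertexOrder)) integer(0) else as.integer(vertexOrder)
  if (length(ord) && !setequal(ord, seq_len(nq) - 1L))
    stop("vertexOrder must be a permutation of the 0-based query vertices")
  res <- cpp_match(adjacencyList(q), adjacencyList(g), cand,
                   mode == "first", as.numeric(maxMatches), ord)
  list(matches = res$matches, states = res$states)
}

#' A deterministic static assignment order for state-count comparisons
#'
#' Breadth-first order of the (connected) query starting from the vertex
#' with the fewest candidates in `compat`, neighbor ties by ascending index.
#' Running the matcher with the same fixed order under two nested
#' compatibility maps guarantees the smaller map explores a subset of the
#' larger map's search states.
#'
#' @inheritParams matchCandidate
#' @return 0-based integer permutation of the query vertices.
#' @export
staticMatchOrder <- function(q, compat) {
  nq <- nVertices(q)
  if (nq == 0L) return(integer(0))
  sizes <- vapply(normalizeCompat(compat, 0L), length, integer(1))
  adj <- adjacencyList(q)
  start <- which.min(sizes)
  seen <- logical(nq)
  seen[start] <- TRUE
  ord <- start
  k <- 1L
  while (k <= length(ord)) {
    nb <- adj[[ord[[k]]]] + 1L
    fresh <- nb[!seen[nb]]
    seen[fresh] <- TRUE
    ord <- c(ord, fresh)
    k <- k + 1L
  }
  ord - 1L
}

#' Run a filter-and-verify query against an indexed database
#'
#' Orchestrates the full pipeline: extract the query's maximal path features
#' ([queryFeatures()]), prune by occurrence counts ([firstStepFilter()]),
#' prune by start-vertex locality ([secondStepFilter()]), then verify each
#' surviving candidate with the locality-constrained backtracking matcher
#' ([matchCandidate()]). In `"first"` mode each matching graph is reported
#' once with one embedding; in `"all"` mode every distinct embedding is
#' enumerated (optionally capped per graph by `maxMatches`).
#'
#' A database holding a single large graph is handled identically: filtering
#' may pass the one graph, and the locality map still constrains the matcher.
#'
#' @param index a [PathIndex-class] built from `db` with the same `lp`.
#' @param db the [GraphDB-class] the index was built from.
#' @param q the query [LabeledGraph-class]; must be connected (a query with
#'   zero vertices trivially matches every graph with the empty embedding).
#' @param mode `"first"` or `"all"`.
#' @param maxMatches per-graph cap on enumerated matches in `"all"` mode.
#' @return a [QueryResult-class].
#' @examples
#' db <- parseGspan(paste("t # g1", "v 0 B", "v 1 A", "v 2 C",
#'                        "e 0 1", "e 1 2", sep = "\n"))
#' idx <- buildIndex(db, 2)
#' q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)))
#' matchedGraphs(runQuery(idx, db, q, "all"))
#' @export
runQuery <- function(index, db, q, mode = c("first", "all"),
                     maxMatches = Inf) {
  stopifnot(is(index, "PathIndex"), is(db, "GraphDB"),
            is(q, "LabeledGraph"))
  mode <- match.arg(mode)
  ids <- graphIds(db)
  if (!identical(ids, index@graphOrder) ||
      !identical(unname(index@vertexCounts[ids]),
                 vapply(db@graphs, nVertices, integer(1))))
    stop("index does not correspond to this database ",
         "(graph ids or vertex counts differ)")
  nq <- nVertices(q)
  if (nq == 0L) {
    return(new("QueryResult", mode = mode, c1 = ids, c2 = ids,
               matches = stats::setNames(
                 rep(list(list(integer(0))), length(ids)), ids),
               states = stats::setNames(numeric(length(ids)), ids),
               nQueryVertices = 0L))
  }
  if (!isConnectedGraph(q))
    stop("disconnected query graphs are not supported")
  qf <- queryFeatures(q, index@lp)
  c1 <- firstStepFilter(index, qf)
  step2 <- secondStepFilter(index, qf, c1)
  matches <- list()
  states <- stats::setNames(numeric(length(step2$candidates)),
                            step2$candidates)
  for (gid in step2$candidates) {
    res <- matchCandidate(q, db[[gid]], step2$compat[[gid]],
                          mode = if (mode == "first") "first" else "all",
                          maxMatches = maxMatches)
    states[[gid]] <- res$states
    if (length(res$matches)) matches[[gid]] <- res$matches
  }
  new("QueryResult", mode = mode, c1 = c1, c2 = step2$candidates,
      matches = matches, states = states, nQueryVertices = nq)
}

#' @rdname QueryResult-class
#' @aliases matchedGraphs,QueryResult-method
setMethod("matchedGraphs", "QueryResult", function(x) names(x@matches))

#' @rdname QueryResult-class
setMethod("matchList", "QueryResult", function(x) x@matches)

#' @rdname QueryResult-class
setMethod("candidates", "QueryResult", function(x, step = 2L) {
  if (step == 1L) x@c1 else x@c2
})

#' @rdname QueryResult-class
setMethod("matcherStates", "QueryResult", function(x) x@states)

#' @export
setMethod("show", "QueryResult", function(object) {
  cat(sprintf(
    "QueryResult (%s mode): |C1| = %d, |C2| = %d, %d graph(s) matched, %d state(s) explored\n",
    object@mode, length(object@c1), length(object@c2),
    length(object@matches), sum(object@states)))
})

#' Format matches as tab-separated lines
#'
#' One line per match: `graph_id<TAB>v0->u0,v1->u1,...` with 0-based vertex
#' indices, the output format of the command-line `query` subcommand.
#'
#' @param result a [QueryResult-class].
#' @return character vector of lines (possibly empty).
#' @export
formatMatches <- function(result) {
  stopifnot(is(result, "QueryResult"))
  unlist(lapply(names(result@matches), function(gid) {
    vapply(result@matches[[gid]], function(m) {
      paste0(gid, "\t",
             paste(sprintf("%d->%d", seq_along(m) - 1L, m), collapse = ","))
    }, character(1))
  }), use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
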