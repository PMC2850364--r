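#' Occurrence-count candidate pruning (first filtering step)
#'
#' Keeps exactly the database graphs that contain every query feature with
#' at least the query's occurrence count:
#' `C1 = intersect over f in FQ of {g in GI[f] : GI[f][g] >= FQ[f]}`.
#' A query feature absent from the global index empties the candidate set;
#' an empty FQ (a query with no vertices) keeps every graph, by the empty
#' intersection convention.
#'
#' @param index a [PathIndex-class].
#' @param fq a [QueryFeatures-class] or a named integer vector of feature
#'   occurrence counts, extracted with the index's `lp`.
#' @return character vector of candidate graph ids, in database order.
#' @examples
#' db <- parseGspan(paste("t # star", "v 0 A", "v 1 B", "v 2 C", "v 3 C",
#'                        "e 0 1", "e 1 2", "e 1 3", sep = "\n"))
#' idx <- buildIndex(db, 3)
#' firstStepFilter(idx, c("A B C" = 2L))
#' @export
firstStepFilter <- function(index, fq) {
  stopifnot(is(index, "PathIndex"))
  if (is(fq, "QueryFeatures")) {
    if (fq@lp != index@lp)
      stop("query features extracted with lp = ", fq@lp,
           " but index was built with lp = ", index@lp)
    fq <- fq@fq
  }
  cand <- index@graphOrder
  for (f in names(fq)) {
    entry <- index@gi[[f]]
    if (is.null(entry)) return(character(0))
    cand <- cand[cand %in% names(entry)[entry >= fq[[f]]]]
    if (length(cand) == 0L) return(character(0))
  }
  cand
}

#' Locality candidate pruning (second filtering step)
#'
#' For each first-step survivor `g` and each query vertex `v`, intersects
#' (bitwise AND) the start bitsets of every feature in `FVQ[v]`:
#' `M[g][v] = intersect over f in FVQ[v] of start(f, g)` — the target
#' vertices compatible with `v`. If any `M[g][v]` is empty, no embedding can
#' map `v` anywhere, so `g` is discarded. A feature of `FVQ[v]` missing from
#' the graph's local index short-circuits `M[g][v]` to the empty set.
#' The surviving `M` is the compatibility map handed to the matcher.
#'
#' @param index a [PathIndex-class].
#' @param fvq a [QueryFeatures-class] (its per-vertex feature sets are used)
#'   or a bare list of per-vertex feature-key vectors.
#' @param c1 candidate ids from [firstStepFilter()] on the same query.
#' @return list with `candidates` (surviving graph ids, database order) and
#'   `compat` (named list: graph id -> list of per-query-vertex raw bitsets).
#' @export
secondStepFilter <- function(index, fvq, c1) {
  stopifnot(is(index, "PathIndex"))
  if (is(fvq, "QueryFeatures")) {
    if (fvq@lp != index@lp)
      stop("query features extracted with lp = ", fvq@lp,
           " but index was built with lp = ", index@lp)
    fvq <- fvq@fvq
  }
  keep <- character(0)
  compat <- list()
  for (gid in c1) {
    li <- index@li[[gid]]
    if (is.null(li)) stop("graph id '", gid, "' not present in index")
    n <- index@vertexCounts[[gid]]
    m <- vector("list", length(fvq))
    alive <- TRUE
    for (v in seq_along(fvq)) {
      feats <- fvq[[v]]
      bits <- li[[feats[[1L]]]]
      if (is.null(bits)) { alive <- FALSE; break }
      for (f in feats[-1L]) {
        nxt <- li[[f]]
        if (is.null(nxt)) { bits <- NULL; break }
        bits <- bits & nxt
        if (!bitsetAny(bits)) break
      }
      if (is.null(bits) || !bitsetAny(bits)) { alive <- FALSE; break }
      m[[v]] <- bits
    }
    if (alive) {
      keep <- c(keep, gid)
      compat[[gid]] <- m
    }
  }
  list(candidates = keep, compat = compat)
}

#' Label-only vertex compatibility
#'
#' The baseline semantic test a plain backtracking matcher uses: a target
#' vertex is compatible with a query vertex iff the labels are equal.
#' Returned in the same per-vertex candidate form the matcher accepts, so
#' locality pruning and label-only matching can be compared directly.
#'
#' @param q query [LabeledGraph-class].
#' @param g target [LabeledGraph-class].
#' @return list, one 0-based integer vector of target candidates per query
#'   vertex.
#' @export
labelCompatibility <- function(q, g) {
  glab <- vertexLabels(g)
  lapply(vertexLabels(q), function(l) which(glab == l) - 1L)
}
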