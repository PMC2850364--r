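INDEX_FORMAT <- "pathquery-index"
INDEX_VERSION <- "1"

#' Build the two-part path-feature index over a database
#'
#' Visits every graph and enumerates, depth-first, all simple paths of at
#' most `lp` vertices. The global index `gi` maps each feature to the graphs
#' containing it with occurrence counts; the local index `li` stores, per
#' graph and feature, the bitset of vertices an occurrence starts from.
#' Features are held in C-locale lexicographic order and graphs in database
#' order, making the index (and its serialization) canonical for a given
#' database and `lp`.
#'
#' @param db a [GraphDB-class].
#' @param lp maximum path length in vertices (default 4; typically <= 10).
#' @return a [PathIndex-class].
#' @examples
#' db <- parseGspan("t # g1\nv 0 A\nv 1 B\ne 0 1")
#' idx <- buildIndex(db, lp = 2)
#' indexFeatures(idx)
#' @export
buildIndex <- function(db, lp = 4L) {
  stopifnot(is(db, "GraphDB"))
  lp <- checkLp(lp)
  ids <- graphIds(db)
  li <- vector("list", length(ids))
  names(li) <- ids
  giCount <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(ids)) {
    g <- db@graphs[[k]]
    res <- cpp_enumerate_features(vertexLabels(g), adjacencyList(g), lp)
    li[[k]] <- stats::setNames(res$starts, res$features)
    feats <- res$features
    cnts <- res$counts
    for (j in seq_along(feats)) {
      prev <- giCount[[feats[[j]]]]
      giCount[[feats[[j]]]] <- c(prev, stats::setNames(cnts[[j]], ids[[k]]))
    }
  }
  fs <- sort(ls(giCount, all.names = TRUE), method = "radix")
  gi <- stats::setNames(lapply(fs, function(f) giCount[[f]]), fs)
  new("PathIndex", lp = lp, formatVersion = INDEX_VERSION, gi = gi, li = li,
      graphOrder = ids,
      vertexCounts = stats::setNames(
        vapply(db@graphs, nVertices, integer(1)), ids))
}

#' @rdname PathIndex-class
#' @aliases indexLp,PathIndex-method
setMethod("indexLp", "PathIndex", function(x) x@lp)

#' @rdname PathIndex-class
setMethod("indexFeatures", "PathIndex", function(x) names(x@gi))

#' @rdname PathIndex-class
setMethod("globalIndex", "PathIndex", function(x) x@gi)

#' @rdname PathIndex-class
setMethod("localIndex", "PathIndex", function(x) x@li)

#' @rdname PathIndex-class
setMethod("graphIds", "PathIndex", function(x) x@graphOrder)

#' @export
setMethod("show", "PathIndex", function(object) {
  cat(sprintf("PathIndex: %d features (lp = %d) over %d graphs\n",
              length(object@gi), object@lp, length(object@graphOrder)))
})

indexChecksum <- function(gi) {
  length(gi) + sum(vapply(gi, function(x) sum(as.numeric(x)), numeric(1)))
}

#' Save and load a path-feature index
#'
#' The on-disk form is a gzip-compressed JSON envelope holding the
#' parameters, the graph order with vertex counts, the global index, and the
#' per-graph start bitsets base64-encoded byte-for-byte in the packed layout
#' (see [bitset]). Loading verifies the format tag, version, an integrity
#' checksum, and — when `expectedLp` is given — that the stored `lp` matches
#' the query pipeline's configuration.
#'
#' @param index a [PathIndex-class].
#' @param path file path.
#' @param expectedLp if non-`NULL`, error unless the stored `lp` equals it.
#' @return `loadIndex()` returns a [PathIndex-class] structurally identical
#'   to the one saved.
#' @examples
#' db <- parseGspan("t # g1\nv 0 A\nv 1 B\ne 0 1")
#' f <- tempfile(fileext = ".json.gz")
#' saveIndex(buildIndex(db, 2), f)
#' loadIndex(f)
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "PathIndex"))
  env <- list(
    format = INDEX_FORMAT,
    version = index@formatVersion,
    lp = index@lp,
    graphs = lapply(index@graphOrder, function(id)
      list(id = id, n = index@vertexCounts[[id]])),
    gi = lapply(index@gi, as.list),
    li = lapply(index@li, function(feats)
      lapply(feats, jsonlite::base64_enc)),
    checksum = indexChecksum(index@gi))
  js <- jsonlite::toJSON(env, auto_unbox = TRUE, digits = NA)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(js, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path, expectedLp = NULL) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  txt <- tryCatch(readLines(con, warn = FALSE),
                  error = function(e) stop("index file unreadable: ",
                                           conditionMessage(e)))
  env <- tryCatch(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                     simplifyVector = FALSE),
                  error = function(e) stop("index file corrupt: ",
                                           conditionMessage(e)))
  if (!identical(env$format, INDEX_FORMAT))
    stop("not a path-feature index file")
  if (!identical(env$version, INDEX_VERSION))
    stop("index format version mismatch: file has '", env$version,
         "', this build reads '", INDEX_VERSION, "'")
  lp <- as.integer(env$lp)
  if (!is.null(expectedLp) && !identical(lp, as.integer(expectedLp)))
    stop("index was built with lp = ", lp, " but the pipeline is configured ",
         "with lp = ", as.integer(expectedLp))
  ids <- vapply(env$graphs, function(x) as.character(x$id), character(1))
  vc <- stats::setNames(vapply(env$graphs, function(x) as.integer(x$n),
                               integer(1)), ids)
  nm <- function(x) if (is.null(names(x))) character(length(x)) else names(x)
  gi <- stats::setNames(lapply(env$gi, function(x)
    stats::setNames(vapply(x, as.integer, integer(1)), nm(x))), nm(env$gi))
  li <- stats::setNames(lapply(env$li, function(feats)
    stats::setNames(lapply(feats, function(b64)
      as.raw(jsonlite::base64_dec(b64))), nm(feats))), nm(env$li))
  if (!isTRUE(all.equal(indexChecksum(gi), as.numeric(env$checksum))))
    stop("index checksum failure: file is corrupt")
  li <- stats::setNames(li[ids], ids)
  new("PathIndex", lp = lp, formatVersion = as.character(env$version),
      gi = gi, li = li, graphOrder = ids, vertexCounts = vc)
}
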