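#' Read and write graph transaction files
#'
#' The transaction format used by the graph-mining community: each graph is a
#' block starting with `t # <id>`, followed by one `v <idx> <label>` line per
#' vertex (indices exactly 0..n-1 in order) and one `e <u> <v>` line per
#' undirected edge. Lines starting with `#` (other than the `#` inside a
#' `t` line) are comments; blank lines are ignored. Files are UTF-8.
#'
#' `writeGspan()` emits a canonical form: graphs in database order, `v` lines
#' by ascending index, `e` lines with `u < v` sorted by `(u, v)`; output is
#' byte-stable so `parse(write(parse(x)))` equals `parse(x)`.
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines.
#' @param path file path.
#' @param db a [GraphDB-class].
#' @return `parseGspan()`/`readGspan()` return a [GraphDB-class];
#'   `writeGspan()` returns the lines invisibly (and writes `path` if given).
#' @examples
#' db <- parseGspan("t # g1\nv 0 A\nv 1 B\ne 0 1")
#' cat(writeGspan(db), sep = "\n")
#' @name gspan-io
NULL

#' @rdname gspan-io
#' @export
parseGspan <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  graphs <- list()
  id <- NULL; labels <- character(0); edges <- list(); seenEdge <- FALSE
  eKeys <- new.env(hash = TRUE, parent = emptyenv())

  flush <- function() {
    if (is.null(id)) return()
    e <- if (length(edges)) do.call(rbind, edges) else NULL
    graphs[[length(graphs) + 1L]] <<- labeledGraph(labels, e, id)
  }

  for (ln in seq_along(text)) {
    line <- trimws(text[[ln]])
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (tok[1L] == "t") {
      if (length(tok) != 3L || tok[2L] != "#")
        stop("line ", ln, ": malformed graph header '", line, "'")
      flush()
      id <- tok[3L]; labels <- character(0); edges <- list()
      seenEdge <- FALSE
      eKeys <- new.env(hash = TRUE, parent = emptyenv())
    } else if (startsWith(line, "#")) {
      next
    } else if (tok[1L] == "v") {
      if (is.null(id)) stop("line ", ln, ": vertex before graph header")
      if (length(tok) != 3L) stop("line ", ln, ": malformed vertex line")
      if (seenEdge) stop("line ", ln, ": vertex declared after edges")
      idx <- suppressWarnings(as.integer(tok[2L]))
      if (is.na(idx) || idx != length(labels))
        stop("line ", ln, ": vertex indices must be 0..n-1 in order")
      labels <- c(labels, tok[3L])
    } else if (tok[1L] == "e") {
      if (is.null(id)) stop("line ", ln, ": edge before graph header")
      if (length(tok) != 3L) stop("line ", ln, ": malformed edge line")
      uv <- suppressWarnings(as.integer(tok[2:3]))
      if (anyNA(uv)) stop("line ", ln, ": malformed edge line")
      if (any(uv < 0L) || any(uv >= length(labels)))
        stop("line ", ln, ": edge references undeclared vertex")
      if (uv[1L] == uv[2L]) stop("line ", ln, ": self-loop not allowed")
      key <- paste(sort(uv), collapse = ",")
      if (!is.null(eKeys[[key]])) stop("line ", ln, ": duplicate edge")
      eKeys[[key]] <- TRUE
      edges[[length(edges) + 1L]] <- uv
      seenEdge <- TRUE
    } else {
      stop("line ", ln, ": unrecognized line '", line, "'")
    }
  }
  flush()
  graphDB(graphs)
}

#' @rdname gspan-io
#' @export
readGspan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parseGspan(readLines(path, encoding = "UTF-8"))
}

#' @rdname gspan-io
#' @export
writeGspan <- function(db, path = NULL) {
  stopifnot(is(db, "GraphDB"))
  lines <- unlist(lapply(db@graphs, function(g) {
    n <- nVertices(g)
    out <- sprintf("t # %s", graphId(g))
    if (n > 0)
      out <- c(out, sprintf("v %d %s", seq_len(n) - 1L, vertexLabels(g)))
    e <- edgeMatrix(g)
    if (nrow(e) > 0)
      out <- c(out, sprintf("e %d %d", e[, 1L], e[, 2L]))
    out
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
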