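# Independent brute-force path enumeration used as the reference for
# occurrence counts, start sets and query features. Deliberately written
# against the plain adjacency matrix, sharing no traversal code with the
# package's depth-first enumerator.

oracleAdjacency <- function(g) {
  n <- nVertices(g)
  A <- matrix(FALSE, n, n)
  e <- edgeMatrix(g)
  if (nrow(e)) {
    A[cbind(e[, 1L] + 1L, e[, 2L] + 1L)] <- TRUE
    A[cbind(e[, 2L] + 1L, e[, 1L] + 1L)] <- TRUE
  }
  A
}

# every simple directed vertex sequence of 1..lp vertices:
# data.frame(key, start0)
oraclePathTable <- function(g, lp) {
  A <- oracleAdjacency(g)
  labs <- vertexLabels(g)
  n <- nrow(A)
  keys <- character(0)
  starts <- integer(0)
  rec <- function(seqv) {
    keys[[length(keys) + 1L]] <<- paste(labs[seqv], collapse = " ")
    starts[[length(starts) + 1L]] <<- seqv[[1L]] - 1L
    if (length(seqv) < lp) {
      last <- seqv[[length(seqv)]]
      for (u in seq_len(n)) {
        if (A[last, u] && !(u %in% seqv)) rec(c(seqv, u))
      }
    }
  }
  for (v in seq_len(n)) rec(v)
  data.frame(key = keys, start = starts, stringsAsFactors = FALSE)
}

oracleCounts <- function(g, lp) {
  tab <- oraclePathTable(g, lp)
  cnt <- table(tab$key)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  out[sort(names(out), method = "radix")]
}

oracleStarts <- function(g, lp) {
  tab <- unique(oraclePathTable(g, lp))
  sp <- split(tab$start, tab$key)
  lapply(sp, function(x) sort(unique(as.integer(x))))
}

# canonical string form of a match set for set-equality assertions
matchSetKey <- function(matches) {
  sort(vapply(matches, paste, character(1), collapse = ","))
}

# small seeded random connected graph drawn through the molecule generator
randomSmallGraph <- function(seed, nmin = 4, nmax = 10, nLabels = 4) {
  genMoleculeDB(1L, c(nmin, nmax), nLabels = nLabels, labelSkew = 0.7,
                seed = seed)[[1L]]
}
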