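#' Brute-force subgraph isomorphism oracle
#'
#' Exhaustive enumeration of every injective, label-preserving assignment of
#' query vertices to target vertices that carries each query edge onto a
#' target edge. Intentionally shares no code with the feature index, the
#' filters or the backtracking matcher — it anchors their correctness tests
#' as an independent reference. Query vertices are assigned in index order,
#' so it is practical for targets of up to roughly a dozen vertices (or for
#' queries whose vertex numbering follows a construction order in which
#' every vertex is adjacent to an earlier one, as the generators here emit).
#'
#' @param q query [LabeledGraph-class].
#' @param g target [LabeledGraph-class].
#' @param limit stop after this many matches (`Inf` = enumerate all).
#' @return list of matches, each a 0-based integer vector mapping query
#'   vertex `i-1` to element `i`.
#' @examples
#' q <- labeledGraph(c("A", "B"), rbind(c(0, 1)))
#' length(bruteForceMatches(q, q))
#' @export
bruteForceMatches <- function(q, g, limit = Inf) {
  stopifnot(is(q, "LabeledGraph"), is(g, "LabeledGraph"))
  nq <- nVertices(q)
  ng <- nVertices(g)
  if (nq == 0L) return(list(integer(0)))
  qlab <- vertexLabels(q)
  glab <- vertexLabels(g)
  A <- matrix(FALSE, ng, ng)
  eg <- edgeMatrix(g)
  if (nrow(eg)) {
    A[cbind(eg[, 1L] + 1L, eg[, 2L] + 1L)] <- TRUE
    A[cbind(eg[, 2L] + 1L, eg[, 1L] + 1L)] <- TRUE
  }
  eq <- edgeMatrix(q)
  prev <- rep(list(integer(0)), nq)  # neighbors with smaller index, 1-based
  if (nrow(eq)) {
    for (r in seq_len(nrow(eq))) {
      a <- eq[r, 1L] + 1L
      b <- eq[r, 2L] + 1L
      prev[[max(a, b)]] <- c(prev[[max(a, b)]], min(a, b))
    }
  }
  cands <- lapply(qlab, function(l) which(glab == l))
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 64L)
  acc$k <- 0L
  map <- integer(nq)
  used <- logical(ng)
  assign1 <- function(v) {
    if (acc$k >= limit) return(invisible())
    for (u in cands[[v]]) {
      if (used[u]) next
      ok <- TRUE
      for (w in prev[[v]]) if (!A[map[w], u]) { ok <- FALSE; break }
      if (!ok) next
      map[v] <<- u
      used[u] <<- TRUE
      if (v == nq) {
        acc$k <- acc$k + 1L
        if (acc$k > length(acc$out))
          acc$out <- c(acc$out, vector("list", length(acc$out)))
        acc$out[[acc$k]] <- map - 1L
      } else {
        assign1(v + 1L)
      }
      used[u] <<- FALSE
      if (acc$k >= limit) return(invisible())
    }
    invisible()
  }
  assign1(1L)
  acc$out[seq_len(acc$k)]
}

defaultLabels <- function(nLabels) paste0("L", seq_len(nLabels))

#' Generate a labeled scale-free network
#'
#' Preferential-attachment growth: vertices are added one at a time, each
#' connected to an existing vertex chosen with probability proportional to
#' its degree (plus-one smoothing so the seed vertex can be chosen); once
#' all vertices exist, additional edges are added with both endpoints drawn
#' preferentially, rejecting self-loops and duplicates, until `nEdges`
#' edges. The result is connected with a heavy-tailed degree distribution.
#' Labels are drawn i.i.d. over `nLabels` symbols, uniformly by default or
#' per `labelProbs`. The output is a pure function of the arguments and
#' `seed`.
#'
#' The default sizes are the benchmark conditions for single-large-graph
#' search: 2000 vertices, about 4000 edges, 8 uniformly distributed labels.
#'
#' @param nNodes number of vertices.
#' @param nEdges total number of edges (must be at least `nNodes - 1`).
#' @param nLabels size of the label alphabet.
#' @param labelProbs optional label frequency vector of length `nLabels`.
#' @param seed integer seed; fully determines the output.
#' @param graphId identifier for the generated graph.
#' @return a connected [LabeledGraph-class].
#' @export
genScaleFree <- function(nNodes = 2000L, nEdges = 4000L, nLabels = 8L,
                         labelProbs = NULL, seed = 1L, graphId = "sf0") {
  nNodes <- as.integer(nNodes)
  nEdges <- as.integer(nEdges)
  stopifnot(nNodes >= 1L)
  if (nEdges < nNodes - 1L)
    stop("nEdges must be at least nNodes - 1 for a connected network")
  if (nEdges > nNodes * (nNodes - 1L) / 2)
    stop("nEdges exceeds the number of vertex pairs")
  withr::with_seed(seed, {
    deg <- integer(nNodes)
    eu <- integer(nEdges)
    ev <- integer(nEdges)
    m <- 0L
    seen <- new.env(hash = TRUE, parent = emptyenv())
    addEdge <- function(a, b) {
      m <<- m + 1L
      eu[m] <<- a
      ev[m] <<- b
      deg[a] <<- deg[a] + 1L
      deg[b] <<- deg[b] + 1L
      seen[[paste(min(a, b), max(a, b))]] <- TRUE
    }
    if (nNodes > 1L) {
      for (t in 2:nNodes) {
        w <- sample.int(t - 1L, 1L, prob = deg[seq_len(t - 1L)] + 1)
        addEdge(w, t)
      }
    }
    tries <- 0L
    maxTries <- 200L * nEdges + 1000L
    while (m < nEdges) {
      u <- sample.int(nNodes, 1L, prob = deg + 1)
      v <- sample.int(nNodes, 1L, prob = deg + 1)
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place the requested number of edges")
      if (u == v) next
      if (!is.null(seen[[paste(min(u, v), max(u, v))]])) next
      addEdge(u, v)
    }
    labs <- sample(defaultLabels(nLabels), nNodes, replace = TRUE,
                   prob = labelProbs)
    labeledGraph(labs, cbind(eu - 1L, ev - 1L), graphId)
  })
}

#' Sample a connected query subgraph breadth-first
#'
#' Starting from a random vertex, repeatedly picks a random unused edge
#' incident to the visited vertex set and adds it, until exactly `tEdges`
#' edges are collected; if the frontier dries up first, a fresh start vertex
#' is drawn (up to `maxRetries` restarts). The sampled vertices are
#' renumbered in first-visit order, so the query is a relabeled copy of a
#' connected subgraph of `g` and is subgraph-isomorphic to `g` by
#' construction.
#'
#' @param g source [LabeledGraph-class] with at least `tEdges` edges.
#' @param tEdges number of query edges (benchmark workloads use 4, 8, 16).
#' @param seed integer seed.
#' @param maxRetries restarts before giving up.
#' @param graphId identifier for the query graph.
#' @return a connected [LabeledGraph-class] with exactly `tEdges` edges.
#' @export
sampleQueryBFS <- function(g, tEdges, seed = 1L, maxRetries = 50L,
                           graphId = "q0") {
  stopifnot(is(g, "LabeledGraph"))
  tEdges <- as.integer(tEdges)
  e <- edgeMatrix(g)
  if (tEdges < 1L || tEdges > nrow(e))
    stop("tEdges must be between 1 and the number of edges of g")
  n <- nVertices(g)
  withr::with_seed(seed, {
    for (try in seq_len(maxRetries)) {
      visited <- logical(n)
      order0 <- integer(0)           # 0-based vertices in visit order
      chosen <- logical(nrow(e))
      start <- sample.int(n, 1L) - 1L
      visited[start + 1L] <- TRUE
      order0 <- start
      ok <- TRUE
      for (k in seq_len(tEdges)) {
        cand <- which(!chosen &
                      (visited[e[, 1L] + 1L] | visited[e[, 2L] + 1L]))
        if (length(cand) == 0L) { ok <- FALSE; break }
        pick <- cand[[sample.int(length(cand), 1L)]]
        chosen[pick] <- TRUE
        for (w in e[pick, ]) {
          if (!visited[w + 1L]) {
            visited[w + 1L] <- TRUE
            order0 <- c(order0, w)
          }
        }
      }
      if (ok) {
        newId <- integer(n)
        newId[order0 + 1L] <- seq_along(order0) - 1L
        qe <- cbind(newId[e[chosen, 1L] + 1L], newId[e[chosen, 2L] + 1L])
        return(labeledGraph(vertexLabels(g)[order0 + 1L], qe, graphId))
      }
    }
    stop("could not sample a connected query with ", tEdges,
         " edges after ", maxRetries, " restarts")
  })
}

#' Generate a database of small sparse molecule-like graphs
#'
#' A synthetic stand-in for databases of small chemical compounds: each
#' graph is a uniform random spanning tree (vertex `i` attaches to a random
#' earlier vertex, so vertex numbering follows construction order) plus
#' about 25% extra random edges, giving sparse connected graphs. Labels are
#' drawn from a geometric-decay categorical distribution with ratio
#' `labelSkew` (1 = uniform; smaller values concentrate mass on the first
#' label, mimicking the dominance of carbon in molecular graphs).
#'
#' @param nGraphs number of graphs.
#' @param sizeRange integer range of per-graph vertex counts.
#' @param nLabels label alphabet size.
#' @param labelSkew geometric decay ratio in (0, 1].
#' @param seed integer seed.
#' @return a [GraphDB-class] of connected graphs.
#' @export
genMoleculeDB <- function(nGraphs = 100L, sizeRange = c(8L, 20L),
                          nLabels = 6L, labelSkew = 0.6, seed = 1L) {
  stopifnot(nGraphs >= 1L, length(sizeRange) == 2L,
            sizeRange[1L] >= 1L, sizeRange[1L] <= sizeRange[2L],
            labelSkew > 0, labelSkew <= 1)
  probs <- labelSkew^(seq_len(nLabels) - 1L)
  probs <- probs / sum(probs)
  alpha <- defaultLabels(nLabels)
  withr::with_seed(seed, {
    graphs <- lapply(seq_len(nGraphs), function(i) {
      sizes <- seq.int(sizeRange[1L], sizeRange[2L])
      n <- sizes[[sample.int(length(sizes), 1L)]]
      eu <- integer(0)
      ev <- integer(0)
      if (n > 1L) {
        eu <- vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1))
        ev <- 2:n
      }
      keys <- paste(eu, ev)
      nExtra <- round(0.25 * n)
      tries <- 0L
      while (nExtra > 0L && tries < 50L * n) {
        tries <- tries + 1L
        uv <- sort(sample.int(n, 2L))
        key <- paste(uv[1L], uv[2L])
        if (key %in% keys) next
        keys <- c(keys, key)
        eu <- c(eu, uv[1L])
        ev <- c(ev, uv[2L])
        nExtra <- nExtra - 1L
      }
      labs <- sample(alpha, n, replace = TRUE, prob = probs)
      edges <- if (length(eu)) cbind(eu - 1L, ev - 1L) else NULL
      labeledGraph(labs, edges, sprintf("m%03d", i - 1L))
    })
    graphDB(graphs)
  })
}

#' A hub query with no embedding in a hub-bearing target
#'
#' Reproduces the pathological workload for plain backtracking matchers on
#' scale-free networks: a 13-vertex, 16-edge query whose central hub has
#' degree 12, and a target network containing a deceptively similar hub.
#' The target hub offers only five neighbors of the second leaf label where
#' the query needs six, so no embedding exists (the other hub-labeled
#' target vertex has low degree) — yet a label-only matcher must explore
#' the hub neighborhood combinatorially before failing, while start-path
#' locality can reject the hub pairing early.
#'
#' @param seed integer seed; permutes the target's vertex numbering.
#' @return list with elements `query` and `target` ([LabeledGraph-class]).
#' @export
hubQueryFixture <- function(seed = 1L) {
  # query: hub 0 (H), leaves 1..6 = X, 7..12 = Y, 4 extra leaf-leaf edges
  qlab <- c("H", rep("X", 6L), rep("Y", 6L))
  qe <- rbind(cbind(0L, 1:12),
              c(1L, 2L), c(3L, 4L), c(7L, 8L), c(9L, 10L))
  q <- labeledGraph(qlab, qe, "hubq")
  # target: hub 0 (H) with 7 X and 5 Y neighbors, matching extra edges on
  # the X side, a low-degree second H, and some padding
  tlab <- c("H", rep("X", 7L), rep("Y", 5L), "H", "Z", "Z", "X")
  te <- rbind(cbind(0L, 1:12),
              c(1L, 2L), c(3L, 4L), c(8L, 9L), c(10L, 11L),
              c(13L, 1L), c(14L, 2L), c(15L, 14L), c(16L, 15L))
  withr::with_seed(seed, {
    n <- length(tlab)
    perm <- sample.int(n) - 1L      # perm[old + 1] = new id
    ord <- order(perm)
    g <- labeledGraph(tlab[ord],
                      cbind(perm[te[, 1L] + 1L], perm[te[, 2L] + 1L]),
                      "hubg")
    list(query = q, target = g)
  })
}
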