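starEdgeDB <- function() {
  star <- labeledGraph(c("A", "B", "C", "C"),
                       rbind(c(0, 1), c(1, 2), c(1, 3)), "star")
  edge <- labeledGraph(c("A", "B"), rbind(c(0, 1)), "edge")
  graphDB(list(star, edge))
}

test_that("occurrence-count pruning applies the C1 formula", {
  idx <- buildIndex(starEdgeDB(), 3)
  expect_equal(firstStepFilter(idx, c("A B C" = 2L)), "star")
  expect_equal(firstStepFilter(idx, c("A B" = 2L)), character(0))
  expect_equal(firstStepFilter(idx, c("A B" = 1L)), c("star", "edge"))
  # empty FQ keeps every graph
  expect_equal(firstStepFilter(idx, stats::setNames(integer(0), character(0))),
               c("star", "edge"))
  # a feature absent from the whole database empties the candidate set
  expect_equal(firstStepFilter(idx, c("Z" = 1L)), character(0))
})

test_that("locality filtering prunes the chain but keeps the branch", {
  g1 <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)), "g1")
  g2 <- labeledGraph(c("B", "A", "A", "C"),
                     rbind(c(0, 1), c(1, 2), c(2, 3)), "g2")
  db <- graphDB(list(g1, g2))
  idx <- buildIndex(db, 2)
  q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)), "q")
  qf <- queryFeatures(q, 2)
  c1 <- firstStepFilter(idx, qf)
  expect_equal(c1, c("g1", "g2"))          # counts alone cannot separate
  s2 <- secondStepFilter(idx, qf, c1)
  expect_equal(s2$candidates, "g1")        # no vertex of g2 starts both
  # M[g1] assigns the A vertex of q to the A vertex of g1
  expect_equal(bitsetIndices(s2$compat$g1[[2L]]), 1L)
  # and the oracle agrees with the filter's verdict
  expect_equal(length(bruteForceMatches(q, g1)), 1L)
  expect_equal(length(bruteForceMatches(q, g2)), 0L)
})

test_that("querying a database graph with itself keeps the identity", {
  db <- genMoleculeDB(8L, c(3L, 9L), seed = 17L)
  idx <- buildIndex(db, 4)
  for (k in c(1L, 4L, 8L)) {
    g <- db[[k]]
    qf <- queryFeatures(g, 4)
    c1 <- firstStepFilter(idx, qf)
    expect_true(graphId(g) %in% c1)
    s2 <- secondStepFilter(idx, qf, c1)
    expect_true(graphId(g) %in% s2$candidates)
    m <- s2$compat[[graphId(g)]]
    for (v in seq_len(nVertices(g)))
      expect_true((v - 1L) %in% bitsetIndices(m[[v]]))
  }
})

test_that("filtering never drops a graph that contains the query", {
  db <- genMoleculeDB(25L, c(4L, 12L), seed = 23L)
  idx <- buildIndex(db, 3)
  for (s in 1:10) {
    src <- db[[1L + (s * 7L) %% 25L]]
    q <- sampleQueryBFS(src, min(4L, numEdges(src)), seed = s)
    qf <- queryFeatures(q, 3)
    c1 <- firstStepFilter(idx, qf)
    s2 <- secondStepFilter(idx, qf, c1)
    expect_true(all(s2$candidates %in% c1))
    truth <- Filter(function(gid)
      length(bruteForceMatches(q, db[[gid]], limit = 1)) > 0, graphIds(db))
    expect_true(all(truth %in% s2$candidates))
  }
})

test_that("adding features to a vertex never grows its compatibility set", {
  g <- genMoleculeDB(1L, c(8L, 12L), seed = 41L)[[1L]]
  db <- graphDB(list(g))
  idx <- buildIndex(db, 3)
  q <- sampleQueryBFS(g, 5L, seed = 3L)
  qf <- queryFeatures(q, 3)
  full <- secondStepFilter(idx, qf, graphIds(db))
  # drop features from each vertex: the intersection can only grow
  for (v in seq_len(nVertices(q))) {
    fvqSmall <- fvqSets(qf)
    fvqSmall[[v]] <- fvqSmall[[v]][1L]
    part <- secondStepFilter(idx, fvqSmall, graphIds(db))
    if (length(full$candidates) && length(part$candidates)) {
      expect_true(all(bitsetIndices(full$compat[[1L]][[v]]) %in%
                      bitsetIndices(part$compat[[1L]][[v]])))
    }
  }
})

test_that("label compatibility is implied by the locality map", {
  g <- genMoleculeDB(1L, c(6L, 10L), seed = 55L)[[1L]]
  db <- graphDB(list(g))
  idx <- buildIndex(db, 3)
  q <- sampleQueryBFS(g, 4L, seed = 9L)
  qf <- queryFeatures(q, 3)
  s2 <- secondStepFilter(idx, qf, graphIds(db))
  lab <- labelCompatibility(q, g)
  for (v in seq_len(nVertices(q)))
    expect_true(all(bitsetIndices(s2$compat[[1L]][[v]]) %in% lab[[v]]))
})
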