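test_that("matcher reproduces exact counts on canonical instances", {
  a1 <- labeledGraph("A")
  res <- matchCandidate(a1, a1, list(0L))
  expect_equal(res$matches, list(0L))

  tri <- labeledGraph(rep("A", 3), rbind(c(0, 1), c(1, 2), c(0, 2)))
  k4 <- labeledGraph(rep("A", 4), t(combn(0:3, 2)))
  res <- matchCandidate(tri, k4, labelCompatibility(tri, k4))
  expect_equal(length(res$matches), 24L)
  expect_equal(matchSetKey(res$matches),
               matchSetKey(bruteForceMatches(tri, k4)))

  # non-induced semantics: a path query embeds into a triangle
  p3 <- labeledGraph(rep("A", 3), rbind(c(0, 1), c(1, 2)))
  expect_equal(length(matchCandidate(p3, tri,
                                     labelCompatibility(p3, tri))$matches),
               6L)
})

test_that("matcher refuses disconnected queries", {
  dq <- labeledGraph(c("A", "B"))
  g <- labeledGraph(c("A", "B"), rbind(c(0, 1)))
  expect_error(matchCandidate(dq, g, labelCompatibility(dq, g)),
               "disconnected")
})

test_that("all-mode match sets equal the oracle on random pairs", {
  for (s in 1:30) {
    g <- randomSmallGraph(s, 4, 10)
    q <- if (s %% 2 == 0) {
      sampleQueryBFS(g, min(3L, numEdges(g)), seed = s)
    } else {
      randomSmallGraph(s + 500, 2, 5)
    }
    res <- matchCandidate(q, g, labelCompatibility(q, g))
    expect_equal(matchSetKey(res$matches),
                 matchSetKey(bruteForceMatches(q, g)),
                 info = paste("seed", s))
  }
})

test_that("first mode returns an element of the all-mode set", {
  for (s in 31:40) {
    g <- randomSmallGraph(s, 5, 10)
    q <- sampleQueryBFS(g, min(4L, numEdges(g)), seed = s)
    compat <- labelCompatibility(q, g)
    all <- matchCandidate(q, g, compat, mode = "all")
    first <- matchCandidate(q, g, compat, mode = "first")
    expect_equal(length(first$matches), 1L)
    expect_true(paste(first$matches[[1L]], collapse = ",") %in%
                matchSetKey(all$matches))
    expect_lte(first$states, all$states)
  }
})

test_that("maxMatches caps enumeration deterministically", {
  g <- labeledGraph(rep("A", 6), t(combn(0:5, 2)))
  q <- labeledGraph(rep("A", 3), rbind(c(0, 1), c(1, 2), c(0, 2)))
  capped <- matchCandidate(q, g, labelCompatibility(q, g), maxMatches = 7)
  expect_equal(length(capped$matches), 7L)
  full <- matchCandidate(q, g, labelCompatibility(q, g))
  expect_equal(capped$matches, full$matches[1:7])
})

test_that("locality compatibility yields the same matches in fewer states", {
  for (s in 41:52) {
    g <- randomSmallGraph(s, 8, 12)
    db <- graphDB(list(g))
    idx <- buildIndex(db, 3)
    q <- if (s %% 2 == 0) sampleQueryBFS(g, min(5L, numEdges(g)), seed = s)
         else randomSmallGraph(s + 900, 3, 6)
    qf <- queryFeatures(q, 3)
    s2 <- secondStepFilter(idx, qf, firstStepFilter(idx, qf))
    lab <- labelCompatibility(q, g)
    if (length(s2$candidates) == 0L) {
      # pruned: the label-only matcher must agree there is nothing to find
      expect_equal(length(matchCandidate(q, g, lab)$matches), 0L)
      next
    }
    loc <- s2$compat[[1L]]
    ord <- staticMatchOrder(q, loc)
    rLoc <- matchCandidate(q, g, loc, vertexOrder = ord)
    rLab <- matchCandidate(q, g, lab, vertexOrder = ord)
    expect_equal(matchSetKey(rLoc$matches), matchSetKey(rLab$matches))
    expect_lte(rLoc$states, rLab$states)
  }
})

test_that("run_query orchestrates filtering and verification", {
  g1 <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)), "g1")
  g2 <- labeledGraph(c("B", "A", "A", "C"),
                     rbind(c(0, 1), c(1, 2), c(2, 3)), "g2")
  db <- graphDB(list(g1, g2))
  idx <- buildIndex(db, 2)
  q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)), "q")
  res <- runQuery(idx, db, q, "all")
  expect_equal(matchedGraphs(res), "g1")
  expect_equal(candidates(res, 1L), c("g1", "g2"))
  expect_equal(candidates(res, 2L), "g1")
  expect_equal(matchList(res)$g1, list(c(0L, 1L, 2L)))

  # self-containment: a member graph queried against its own db
  db2 <- genMoleculeDB(10L, c(3L, 9L), seed = 77L)
  idx2 <- buildIndex(db2, 4)
  res2 <- runQuery(idx2, db2, db2[[4L]], "first")
  expect_true(graphId(db2[[4L]]) %in% matchedGraphs(res2))

  # index/db mismatch is refused
  expect_error(runQuery(idx, db2, q), "does not correspond")

  # zero-vertex query trivially matches everything with the empty embedding
  res0 <- runQuery(idx, db, labeledGraph(character(0)), "all")
  expect_equal(matchedGraphs(res0), c("g1", "g2"))
  expect_equal(matchList(res0)$g1, list(integer(0)))
})

test_that("match lines serialize as graph id plus assignment pairs", {
  db <- graphDB(list(labeledGraph(c("A", "B"), rbind(c(0, 1)), "g")))
  idx <- buildIndex(db, 2)
  q <- labeledGraph(c("A", "B"), rbind(c(0, 1)))
  out <- formatMatches(runQuery(idx, db, q, "all"))
  expect_equal(out, "g\t0->0,1->1")
})
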