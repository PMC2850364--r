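test_that("brute-force oracle is exact on canonical instances", {
  e <- labeledGraph(c("A", "B"), rbind(c(0, 1)))
  expect_equal(bruteForceMatches(e, e), list(c(0L, 1L)))

  tri <- labeledGraph(rep("A", 3), rbind(c(0, 1), c(1, 2), c(0, 2)))
  k4 <- labeledGraph(rep("A", 4), t(combn(0:3, 2)))
  expect_equal(length(bruteForceMatches(tri, k4)), 24L)

  q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)))
  g2 <- labeledGraph(c("B", "A", "A", "C"),
                     rbind(c(0, 1), c(1, 2), c(2, 3)))
  expect_equal(length(bruteForceMatches(q, g2)), 0L)

  expect_equal(length(bruteForceMatches(tri, k4, limit = 5)), 5L)
})

test_that("scale-free generation is seeded, connected and heavy-tailed", {
  tiny <- genScaleFree(2, 1, 2, seed = 3)
  expect_equal(numEdges(tiny), 1L)

  g1 <- genScaleFree(300, 600, 8, seed = 5)
  g2 <- genScaleFree(300, 600, 8, seed = 5)
  expect_identical(writeGspan(graphDB(list(g1))),
                   writeGspan(graphDB(list(g2))))
  expect_false(identical(edgeMatrix(g1),
                         edgeMatrix(genScaleFree(300, 600, 8, seed = 6))))

  # connectivity: tree phase touches every vertex
  reach <- function(g) {
    adj <- adjacencyList(g)
    seen <- logical(nVertices(g)); seen[1] <- TRUE; q <- 1L
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      nb <- adj[[v]] + 1L; fr <- nb[!seen[nb]]; seen[fr] <- TRUE
      q <- c(q, fr)
    }
    all(seen)
  }
  expect_true(reach(g1))

  # degree variance well above the same-size uniform-attachment baseline
  degVar <- function(g) stats::var(lengths(adjacencyList(g)))
  prefVars <- vapply(1:10, function(s)
    degVar(genScaleFree(300, 600, 8, seed = s)), numeric(1))
  erVars <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      deg <- tabulate(sample.int(300, 1200, replace = TRUE), 300)
    })
    stats::var(deg)
  }, numeric(1))
  expect_gt(mean(prefVars), mean(erVars))

  expect_error(genScaleFree(10, 3, 2, seed = 1), "at least")
})

test_that("generated labels are close to the requested distribution", {
  counts <- integer(8)
  for (s in 1:10) {
    labs <- vertexLabels(genScaleFree(500, 800, 8, seed = 100 + s))
    counts <- counts + as.integer(table(factor(labs, paste0("L", 1:8))))
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("breadth-first sampled queries are embedded subgraphs", {
  g <- genScaleFree(200, 400, 8, seed = 11)
  q1 <- sampleQueryBFS(g, 1L, seed = 2)
  expect_equal(numEdges(q1), 1L)
  ek <- apply(edgeMatrix(g), 1, function(r)
    paste(sort(vertexLabels(g)[r + 1L]), collapse = "|"))
  qk <- paste(sort(vertexLabels(q1)), collapse = "|")
  expect_true(qk %in% ek)

  for (t in c(4L, 8L, 16L)) {
    q <- sampleQueryBFS(g, t, seed = t)
    expect_equal(numEdges(q), t)
    expect_gte(length(bruteForceMatches(q, g, limit = 1)), 1L)
    # reproducible
    expect_identical(writeGspan(graphDB(list(q))),
                     writeGspan(graphDB(list(sampleQueryBFS(g, t, seed = t)))))
  }
  expect_error(sampleQueryBFS(g, 10000L, seed = 1), "between 1 and")
})

test_that("molecule-like databases are connected, sparse and reproducible", {
  db <- genMoleculeDB(1L, c(1L, 1L), seed = 4L)
  expect_equal(nVertices(db[[1L]]), 1L)
  expect_equal(numEdges(db[[1L]]), 0L)

  db <- genMoleculeDB(30L, c(5L, 15L), seed = 8L)
  expect_equal(length(db), 30L)
  lines <- writeGspan(db)
  expect_identical(writeGspan(parseGspan(lines)), lines)
  for (k in seq_len(30L)) {
    g <- db[[k]]
    expect_gte(numEdges(g), nVertices(g) - 1L)
    expect_gte(length(bruteForceMatches(
      labeledGraph(vertexLabels(g)[1L]), g, limit = 1)), 1L)
  }
  expect_identical(writeGspan(genMoleculeDB(30L, c(5L, 15L), seed = 8L)),
                   lines)
})

test_that("the hub fixture has a degree-12 hub and no embedding", {
  fx <- hubQueryFixture(seed = 6)
  q <- fx$query
  g <- fx$target
  expect_equal(nVertices(q), 13L)
  expect_equal(numEdges(q), 16L)
  expect_equal(max(lengths(adjacencyList(q))), 12L)
  expect_equal(length(bruteForceMatches(q, g)), 0L)

  # locality matching explores no more states than label-only matching
  db <- graphDB(list(g))
  idx <- buildIndex(db, 4)
  qf <- queryFeatures(q, 4)
  s2 <- secondStepFilter(idx, qf, firstStepFilter(idx, qf))
  lab <- labelCompatibility(q, g)
  if (length(s2$candidates)) {
    ord <- staticMatchOrder(q, s2$compat[[1L]])
    rLoc <- matchCandidate(q, g, s2$compat[[1L]], vertexOrder = ord)
    rLab <- matchCandidate(q, g, lab, vertexOrder = ord)
    expect_equal(length(rLoc$matches), 0L)
    expect_equal(length(rLab$matches), 0L)
    expect_lte(rLoc$states, rLab$states)
  } else {
    succeed("filter pruned the target outright")
  }
})
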