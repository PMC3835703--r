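noEdges <- data.frame(from = character(), to = character(),
                      interaction = character())

posMatrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("x", "y", "z")
  m
}

test_that("force closed forms: repulsion k^2/d, equilibrium at d = k", {
  k <- 1
  ## single node: zero displacement
  p1 <- posMatrix(a = c(0, 0, 0))
  d1 <- computeDisplacements(p1, noEdges, layoutParams(), temperature = Inf)
  expect_equal(unname(d1$displacements), matrix(0, 1, 3))

  ## two isolated nodes at distance 2k: pushed apart with magnitude k/2
  p2 <- posMatrix(a = c(0, 0, 0), b = c(2 * k, 0, 0))
  d2 <- computeDisplacements(p2, noEdges, layoutParams(), temperature = Inf)
  expect_equal(d2$displacements["a", ], c(x = -k / 2, y = 0, z = 0))
  expect_equal(d2$displacements["b", ], c(x = k / 2, y = 0, z = 0))
  expect_equal(d2$repulsionEvals, 1)

  ## connected pair at distance exactly k: attraction and repulsion cancel
  p3 <- posMatrix(a = c(0, 0, 0), b = c(k, 0, 0))
  d3 <- computeDisplacements(p3, data.frame(from = "a", to = "b",
                                            interaction = "pp"),
                             layoutParams(), temperature = Inf)
  expect_equal(max(abs(d3$displacements)), 0)
})

test_that("displacements are capped at the temperature and reject non-finite input", {
  p <- posMatrix(a = c(0, 0, 0), b = c(0.1, 0, 0))
  d <- computeDisplacements(p, noEdges, layoutParams(), temperature = 0.05)
  expect_equal(sqrt(sum(d$displacements["a", ]^2)), 0.05)

  pBad <- posMatrix(a = c(0, 0, 0), b = c(NaN, 0, 0))
  expect_error(computeDisplacements(pBad, noEdges, layoutParams()), "b",
               class = "netscene3dNumericError")
})

test_that("one force pass equals the brute-force double-loop oracle to 1e-9", {
  for (s in 1:10) {
    n <- 2 + (s %% 11)
    g <- randomGraph(n, min(2 * n, n * (n - 1) / 2), seed = 300 + s)
    set.seed(s)
    st <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    rownames(st) <- nodeIds(g)
    colnames(st) <- c("x", "y", "z")
    got <- computeDisplacements(st, graphEdges(g), layoutParams(),
                                temperature = Inf)$displacements
    want <- bruteForceDisplacements(st, graphEdges(g), k = 1)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("the embedder reaches the analytic equilibria of small systems", {
  ## connected pair converges to distance k within 5%
  pair <- readSIF(text = "A pp B")
  st <- frLayout(pair, layoutParams(seed = 1))
  d <- sqrt(sum((st@positions[1, ] - st@positions[2, ])^2))
  expect_lt(abs(d - 1), 0.05)

  ## triangle: three equal pairwise distances (CV < 5%)
  k3 <- triangleGraph()
  q <- layoutQuality(k3, frLayout(k3, layoutParams(seed = 3)))
  expect_lt(q$edgeLengthCV, 0.05)

  ## single node sits at the origin
  solo <- frLayout(netGraph(nodes = "s"), layoutParams(seed = 2))
  expect_equal(unname(solo@positions), matrix(0, 1, 3))
})

test_that("layouts are bit-for-bit deterministic for a fixed seed", {
  g <- randomGraph(40, 70, seed = 8)
  a <- frLayout(g, layoutParams(seed = 9))
  b <- frLayout(g, layoutParams(seed = 9))
  expect_identical(a@positions, b@positions)

  big <- randomGraph(130, 260, seed = 8)
  m1 <- multilevelLayout(big, layoutParams(seed = 10))
  m2 <- multilevelLayout(big, layoutParams(seed = 10))
  expect_identical(m1@positions, m2@positions)
  ## a different seed moves the layout
  m3 <- multilevelLayout(big, layoutParams(seed = 11))
  expect_false(identical(m1@positions, m3@positions))
})

test_that("small graphs bypass coarsening: multilevel equals single-level exactly", {
  g <- randomGraph(30, 45, seed = 12)
  expect_identical(multilevelLayout(g, layoutParams(seed = 5))@positions,
                   frLayout(g, layoutParams(seed = 5))@positions)
})

test_that("a 20-ring lays out with near-uniform edge lengths", {
  ring <- ringGraph(20)
  q <- layoutQuality(ring, multilevelLayout(ring, layoutParams(seed = 5)))
  expect_lt(q$edgeLengthCV, 0.15)
})

test_that("greedy matching coarsening collapses pairs as hand-traced", {
  ## 2-node, 1-edge graph -> one supernode, no edges
  tiny <- coarsenGraph(readSIF(text = "a pp b"), edgeOrder = "sorted")
  expect_equal(numNodes(tiny@coarseGraph), 1)
  expect_equal(numEdges(tiny@coarseGraph), 0)

  ## path a-b-c-d with id-sorted order -> {ab}, {cd}, one edge
  p4 <- netGraph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                            interaction = "pp"))
  cl <- coarsenGraph(p4, edgeOrder = "sorted")
  expect_equal(nodeIds(cl@coarseGraph), c("a", "c"))
  expect_equal(numEdges(cl@coarseGraph), 1)
  expect_equal(unname(cl@parentMap[c("a", "b", "c", "d")]),
               c("a", "a", "c", "c"))

  ## triangle -> 2 coarse nodes, 1 merged edge (weight 2), no self-loop
  cl3 <- coarsenGraph(triangleGraph(), edgeOrder = "sorted")
  expect_equal(numNodes(cl3@coarseGraph), 2)
  expect_equal(numEdges(cl3@coarseGraph), 1)
  expect_equal(graphEdges(cl3@coarseGraph)$weight, 2)
  e <- graphEdges(cl3@coarseGraph)
  expect_true(all(e$from != e$to))
})

test_that("coarsening makes strict progress and preserves connectivity", {
  toIgraph <- function(g) {
    igraph::graph_from_data_frame(graphEdges(g)[, c("from", "to")],
                                  directed = FALSE,
                                  vertices = nodeIds(g))
  }
  for (s in 1:5) {
    g <- randomGraph(60, 100, seed = 400 + s)
    cl <- coarsenGraph(g, seed = s)
    expect_lt(numNodes(cl@coarseGraph), numNodes(g))
    expect_true(all(sort(unique(cl@parentMap)) == nodeIds(cl@coarseGraph)))
    nc <- igraph::components(toIgraph(g))$no
    ncc <- igraph::components(toIgraph(cl@coarseGraph))$no
    expect_equal(ncc, nc)
  }
})

test_that("prolongation keeps children near parents and never coincident", {
  g <- randomGraph(40, 80, seed = 13)
  cl <- coarsenGraph(g, seed = 13)
  st <- frLayout(cl@coarseGraph, layoutParams(seed = 13))
  jr <- 0.25
  pos <- prolongPositions(cl, st, jitterRadius = jr, seed = 14)
  expect_setequal(rownames(pos), nodeIds(g))
  ## every child within jitterRadius of its parent
  off <- pos - st@positions[cl@parentMap[rownames(pos)], , drop = FALSE]
  expect_true(all(sqrt(rowSums(off^2)) <= jr + 1e-9))
  ## siblings within 2 * jitterRadius, and no exact coincidences
  expect_gt(min(dist(pos)), 0)
  sibs <- split(rownames(pos), cl@parentMap[rownames(pos)])
  for (sset in sibs[lengths(sibs) == 2]) {
    d <- sqrt(sum((pos[sset[1], ] - pos[sset[2], ])^2))
    expect_lte(d, 2 * jr + 1e-9)
  }

  orphan <- new("CoarseningLevel", coarseGraph = cl@coarseGraph,
                parentMap = cl@parentMap)
  tooFew <- st@positions[-1, , drop = FALSE]
  expect_error(prolongPositions(orphan, tooFew, jitterRadius = jr),
               class = "netscene3dLookupError")
})

test_that("layout quality metrics match hand-computed values", {
  pair <- readSIF(text = "a pp b")
  st <- new("LayoutState",
            positions = posMatrix(a = c(0, 0, 0), b = c(1, 0, 0)),
            params = list(), forceEvaluations = 0, evalLog = data.frame())
  q <- layoutQuality(pair, st)
  expect_equal(q$edgeLengthMean, 1)
  expect_equal(q$edgeLengthCV, 0)
  expect_equal(q$minSeparation, 1)

  degenerate <- new("LayoutState",
                    positions = posMatrix(a = c(0, 0, 0), b = c(0, 0, 0)),
                    params = list(), forceEvaluations = 0,
                    evalLog = data.frame())
  expect_equal(layoutQuality(netGraph(nodes = c("a", "b")),
                             degenerate)$minSeparation, 0)
})
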