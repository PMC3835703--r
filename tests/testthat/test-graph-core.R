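test_that("graph construction auto-creates endpoints and never leaves dangling edges", {
  g <- netGraph(data.frame(from = c("A", "A"), to = c("B", "C"),
                           interaction = "pp"))
  expect_equal(numNodes(g), 3)
  expect_equal(numEdges(g), 2)
  expect_true(all(c(graphEdges(g)$from, graphEdges(g)$to) %in% nodeIds(g)))

  ## random edge lists: construction is always valid
  for (s in 1:5) {
    g <- randomGraph(15, 20, seed = s)
    expect_true(validObject(g))
  }
})

test_that("duplicate edges collapse to one, keeping last-seen attributes", {
  g <- netGraph(data.frame(from = c("A", "A"), to = c("B", "B"),
                           interaction = "pp", w = c(1, 7)))
  expect_equal(numEdges(g), 1)
  expect_equal(getAttributes(g, edgeKeys(g))$w, 7)
})

test_that("undirected mode identifies (a,b,i) with (b,a,i); directed keeps both", {
  u <- netGraph(data.frame(from = c("A", "B"), to = c("B", "A"),
                           interaction = "pp"))
  expect_equal(numEdges(u), 1)
  d <- netGraph(data.frame(from = c("A", "B"), to = c("B", "A"),
                           interaction = "pp"), directed = TRUE)
  expect_equal(numEdges(d), 2)
})

test_that("node search is a case-insensitive substring match, sorted, layout-invariant", {
  g <- netGraph(nodes = c("A1", "A2", "B1"))
  expect_equal(findNodes(g, "a"), c("A1", "A2"))
  expect_equal(findNodes(netGraph(nodes = "A1"), "zzz"), character())
  contigs <- netGraph(nodes = c("contig510", "contig511"))
  expect_equal(findNodes(contigs, "510"), "contig510")

  ## idempotence and invariance under scene/layout state
  hits <- findNodes(g, "1")
  expect_equal(findNodes(g, "1"), hits)
  sc <- sceneFor(g)
  sc <- highlightNodes(sc, hits)
  expect_equal(findNodes(sc@graph, "1"), hits)
  expect_equal(sort(sc@highlighted), sort(hits))
  ## highlighting adds a label and changes nothing else
  sc0 <- sceneFor(g)
  expect_identical(sc@layout@positions, sc0@layout@positions)
  expect_identical(sc@nodeSize, sc0@nodeSize)
})

test_that("attribute lookup returns full mappings and errors on unknown ids", {
  g <- netGraph(data.frame(from = "A", to = "B", interaction = "pp"),
                nodes = data.frame(id = c("A", "B"), w = c(1.5, NA)))
  expect_equal(getAttributes(g, "A"), list(w = 1.5))
  expect_equal(getAttributes(g, "B"), setNames(list(), character()))
  expect_error(getAttributes(g, "Q"), "Q", class = "netscene3dLookupError")
  expect_equal(getAttributes(g, "A|pp|B"), setNames(list(), character()))
})

test_that("induced subgraphs keep exactly the internal edges", {
  g <- readSIF(text = c("a pp b", "b pp c", "c pp d"))
  s <- inducedSubgraph(g, c("a", "b", "d"))
  expect_equal(nodeIds(s), c("a", "b", "d"))
  expect_equal(edgeKeys(s), "a|pp|b")
  expect_error(inducedSubgraph(g, "zz"), class = "netscene3dLookupError")
})
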