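asmFromArcs <- function(arcs, nNodes = max(abs(unlist(arcs[1:2])))) {
  new("AssemblyGraph",
      nodes = data.frame(id = seq_len(nNodes), length = rep(10, nNodes),
                         cov1 = rep(100, nNodes)),
      arcs = data.frame(from = arcs$from, to = arcs$to,
                        multiplicity = arcs$multiplicity),
      hashLength = 21, sequenceCount = 10, sequences = list())
}

test_that("orientation folding merges reverse-complement twin arcs", {
  asm <- asmFromArcs(data.frame(from = c(1, -2), to = c(2, -1),
                                multiplicity = c(3, 4)))
  g <- assemblyToGraph(asm)
  expect_equal(numEdges(g), 1)
  expect_equal(edgeKeys(g), "1|arc|2")
  expect_equal(getAttributes(g, "1|arc|2")$multiplicity, 7)
  ## twin arcs agree on end labels after folding
  expect_false("mixed" %in% unlist(graphEdges(g)[c("end_source", "end_target")]))
})

test_that("sign folding, self-arcs and isolated nodes convert faithfully", {
  g <- assemblyToGraph(asmFromArcs(data.frame(from = 1, to = -2,
                                              multiplicity = 1)))
  expect_equal(edgeKeys(g), "1|arc|2")

  self <- assemblyToGraph(asmFromArcs(data.frame(from = 2, to = -2,
                                                 multiplicity = 5)))
  e <- graphEdges(self)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, e$to)

  iso <- assemblyToGraph(asmFromArcs(data.frame(from = integer(),
                                                to = integer(),
                                                multiplicity = numeric()),
                                     nNodes = 3))
  expect_equal(numNodes(iso), 3)
  expect_equal(numEdges(iso), 0)
  ## node attributes carry length and coverage
  expect_equal(getAttributes(iso, "1")$length, 10)
  expect_equal(getAttributes(iso, "1")$cov1, 100)
})

test_that("conversion never yields more edges than arcs", {
  for (s in 1:5) {
    asm <- readLastGraph(text = syntheticAssembly(25, 2, seed = 600 + s))
    expect_lte(numEdges(assemblyToGraph(asm)), nrow(asm@arcs))
  }
})

test_that("orientation-kept conversion is a directed graph on signed ids", {
  asm <- asmFromArcs(data.frame(from = c(1, -2), to = c(2, -1),
                                multiplicity = c(3, 4)))
  g <- assemblyToGraph(asm, keepOrientation = TRUE)
  expect_true(isDirected(g))
  expect_equal(numEdges(g), 2)
  expect_true(all(c("1", "-1", "2", "-2") %in% nodeIds(g)))
})

test_that("the minimal diamond is one bubble; a simple path has none", {
  b <- detectBubbles(diamondGraph())
  expect_equal(nrow(b), 1)
  expect_equal(b$nPaths, 2L)
  expect_setequal(unique(unlist(b$paths[[1]])), c("s", "a", "b", "t"))

  expect_equal(nrow(detectBubbles(pathGraph(10))), 0)
  expect_error(detectBubbles(diamondGraph(), maxPathLen = 1),
               class = "netscene3dParameterError")
})

test_that("an embedded diamond is reported from its branching endpoints", {
  emb <- readSIF(text = c("x pp s", "s pp a", "a pp t", "s pp b", "b pp t",
                          "t pp y"))
  b <- detectBubbles(emb)
  expect_equal(nrow(b), 1)
  expect_equal(b$source, "s")
  expect_equal(b$sink, "t")
})

test_that("nested bubbles count separately per distinct endpoint pair", {
  ## s-t has three arms; one arm forks again between a and t: two distinct
  ## reconvergent structures (distinguished by their spanned node sets)
  g <- readSIF(text = c("s pp a", "a pp t", "s pp b", "b pp t",
                        "a pp c", "c pp t"))
  b <- detectBubbles(g)
  expect_equal(nrow(b), 2)
  sets <- vapply(b$paths, function(ps) {
    paste(sort(unique(unlist(ps))), collapse = ",")
  }, character(1))
  expect_true("a,b,s,t" %in% sets)
  expect_equal(anyDuplicated(sets), 0)
})

test_that("bubble detection equals the exhaustive path-pair oracle on random graphs", {
  for (s in 1:25) {
    set.seed(700 + s)
    n <- sample(6:24, 1)
    m <- min(sample(n:(2 * n), 1), n * (n - 1) / 2)
    g <- randomGraph(n, m, seed = 700 + s)
    got <- detectBubbles(g, maxPathLen = 6)
    want <- oracleBubbles(g, maxLen = 6)
    expect_equal(nrow(got), nrow(want))
    expect_equal(paste(got$source, got$sink, got$nPaths),
                 paste(want$source, want$sink, want$nPaths))
  }
})

test_that("bubble counts are invariant under node relabelling", {
  g <- assemblyToGraph(readLastGraph(text = syntheticAssembly(24, 2, seed = 77)))
  nB <- nrow(detectBubbles(g))
  set.seed(78)
  for (rep in 1:3) {
    perm <- sample(numNodes(g))
    mapping <- setNames(sprintf("q%03d", perm), nodeIds(g))
    e <- graphEdges(g)
    relab <- netGraph(data.frame(from = mapping[e$from], to = mapping[e$to],
                                 interaction = e$interaction),
                      nodes = unname(mapping))
    expect_equal(nrow(detectBubbles(relab)), nB)
  }
})

test_that("connection reports group neighbours by contig end with multiplicities", {
  star <- netGraph(data.frame(from = "hub", to = paste0("leaf", 1:5),
                              interaction = "arc"))
  r <- connectionReport(star, "hub")
  expect_equal(nrow(r), 5)
  expect_true(all(r$multiplicity == 1))

  expect_equal(nrow(connectionReport(netGraph(nodes = "iso"), "iso")), 0)
  expect_error(connectionReport(star, "nope"),
               class = "netscene3dLookupError")

  ## merged parallel arcs: counts reflect summed multiplicities per end
  asm <- asmFromArcs(data.frame(from = c(1, 1, -1, 2), to = c(2, -2, 3, 3),
                                multiplicity = c(2, 3, 4, 1)))
  g <- assemblyToGraph(asm)
  r1 <- connectionReport(g, "1")
  expect_equal(sum(r1$multiplicity[r1$neighbor == "2"]), 5)
  expect_equal(sum(r1$multiplicity[r1$neighbor == "3"]), 4)
  ## arc (1,2) leaves 1 by its 3' end; arc (-1,3) by its 5' end
  expect_equal(r1$end[r1$neighbor == "3"], "5p")
})
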