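test_that("diffing a scene against itself is empty; single changes give single events", {
  g <- randomGraph(8, 10, seed = 81)
  sc <- sceneFor(g, seed = 81)
  expect_length(sceneDiff(sc, sc), 0)

  ## one node added: exactly one insert event
  g2 <- netGraph(graphEdges(g), nodes = c(nodeIds(g), "extra"))
  pos2 <- rbind(sc@layout@positions, extra = c(0, 0, 0))
  sc2 <- makeScene(g2, new("LayoutState", positions = pos2, params = list(),
                           forceEvaluations = 0, evalLog = data.frame()))
  ev <- sceneDiff(sc, sc2)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "insert")
  expect_equal(ev[[1]]$target, "node")

  ## one colour change: one style update, no structural events
  sc3 <- sc
  sc3@nodeColor[1] <- "#FF0000"
  ev3 <- sceneDiff(sc, sc3)
  expect_length(ev3, 1)
  expect_equal(ev3[[1]]$kind, "update")
  expect_equal(ev3[[1]]$target, "style")
})

test_that("apply is the exact inverse of diff (groupoid law) on random scene pairs", {
  for (s in 1:8) {
    g <- randomGraph(12, 16, seed = 900 + s)
    x <- sceneFor(g, seed = s)
    keep <- sort(sample(nodeIds(g), 8))
    y <- makeScene(inducedSubgraph(g, keep),
                   frLayout(inducedSubgraph(g, keep), layoutParams(seed = s + 1)),
                   highlighted = keep[1],
                   nodeColor = setNames("#112233", keep[2]))
    expect_true(sceneIdentical(applyEvents(x, sceneDiff(x, y)), y))
    ## identity
    expect_true(sceneIdentical(applyEvents(x, list()), x, ignoreSequence = FALSE))
  }
})

test_that("stale, out-of-order and conflicting events are rejected with their sequence", {
  g <- randomGraph(6, 6, seed = 91)
  x <- sceneFor(g, seed = 91)
  y <- highlightNodes(x, nodeIds(g)[1])
  ev <- sceneDiff(x, y)
  applied <- applyEvents(x, ev)
  expect_error(applyEvents(applied, ev), "stale",
               class = "netscene3dSyncError")

  gap <- ev
  gap[[1]]$seq <- 5
  expect_error(applyEvents(x, gap), "out-of-order",
               class = "netscene3dSyncError")

  dup <- list(list(seq = x@sequence + 1, kind = "insert", target = "node",
                   id = nodeIds(g)[1],
                   payload = list(id = nodeIds(g)[1], x = 0, y = 0, z = 0,
                                  size = 25, color = "#AAAAAA",
                                  highlighted = FALSE, attributes = list())))
  expect_error(applyEvents(x, dup), "exist", class = "netscene3dSyncError")
})

test_that("clients consuming the same stream converge to identical scenes", {
  g <- randomGraph(10, 14, seed = 101)
  server <- syncServer(sceneFor(g, seed = 101))
  c1 <- connectClient(server)

  ## one client, one node insert: the client scene gains that node
  g2 <- netGraph(graphEdges(server$scene@graph),
                 nodes = c(nodeIds(g), "newNode"))
  pos2 <- rbind(server$scene@layout@positions, newNode = c(1, 1, 1))
  publishScene(server, makeScene(g2, new("LayoutState", positions = pos2,
                                         params = list(), forceEvaluations = 0,
                                         evalLog = data.frame())))
  s1 <- clientSync(c1)
  expect_true("newNode" %in% nodeIds(s1@graph))

  ## second client and more mutations: byte-identical serialized scenes
  c2 <- connectClient(server)
  publishScene(server, highlightNodes(server$scene, "newNode"))
  publishScene(server, makeScene(inducedSubgraph(g2, nodeIds(g)),
                                 server$scene@layout))
  expect_identical(exportScene(clientSync(c1)), exportScene(clientSync(c2)))
  expect_true(sceneIdentical(clientScene(c1), server$scene,
                             ignoreSequence = FALSE))

  ## a late joiner converges to the same state as a from-start client
  c3 <- connectClient(server)
  expect_identical(exportScene(clientSync(c3)), exportScene(clientScene(c1)))
})

test_that("snapshot+deltas streams replay to the server state from any join point", {
  g <- randomGraph(9, 12, seed = 111)
  server <- syncServer(sceneFor(g, seed = 111))
  publishScene(server, highlightNodes(server$scene, nodeIds(g)[1]))
  publishScene(server, makeScene(inducedSubgraph(g, nodeIds(g)[-1]),
                                 server$scene@layout))

  full <- readSceneStream(text = writeSceneStream(server))
  expect_true(sceneIdentical(full, server$scene, ignoreSequence = FALSE))

  ## join after the first event: snapshot is the rewound scene
  mid <- readSceneStream(text = writeSceneStream(server, from = 1))
  expect_true(sceneIdentical(mid, server$scene, ignoreSequence = FALSE))

  ## streams survive a file round trip (the CLI serve/mirror path)
  f <- tempfile(fileext = ".ndjson")
  writeSceneStream(server, f)
  expect_true(sceneIdentical(readSceneStream(f), server$scene,
                             ignoreSequence = FALSE))
})
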