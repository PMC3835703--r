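test_that("value-to-size mapping is affine onto the range, midpoint for constants", {
  style <- visualStyle(sizeRange = c(10, 40))
  expect_equal(mapValuesToSize(c(a = 0, b = 1), style), c(a = 10, b = 40))
  expect_equal(mapValuesToSize(c(a = 5, b = 5), style), c(a = 25, b = 25))
  expect_equal(mapValuesToSize(c(a = 0, b = 2, c = 4), c(0, 1)),
               c(a = 0, b = 0.5, c = 1))
  expect_error(mapValuesToSize(c(a = 1, b = Inf), style), "b",
               class = "netscene3dNumericError")
})

test_that("affine mapping preserves value order (monotonicity property)", {
  set.seed(21)
  for (rep in 1:5) {
    v <- setNames(rnorm(20), paste0("n", 1:20))
    s <- mapValuesToThickness(v, visualStyle())
    expect_equal(order(v), order(s))
  }
})

test_that("colour mapping anchors the ramp at min, mid and max", {
  v <- c(lo = -2, mid = 1, hi = 4)
  cols <- mapValuesToColor(v, "heatmap")
  expect_equal(unname(cols["lo"]), "#0000FF")
  expect_equal(unname(cols["mid"]), "#000000")
  expect_equal(unname(cols["hi"]), "#FFFF00")
  custom <- mapValuesToColor(v, c("#FF0000", "#FFFFFF", "#00FF00"))
  expect_equal(unname(custom["mid"]), "#FFFFFF")
  expect_error(mapValuesToColor(v, "no-such-scheme"),
               class = "netscene3dConfigError")
})

test_that("positive-value filtering keeps exactly the strictly-positive elements", {
  g <- readSIF(text = c("s pp a", "s pp b"))
  fluxes <- attributeTable("Flux", c("a|pp|s" = 2.5, "b|pp|s" = 0))
  f <- suppressMessages(filterPositive(g, fluxes))
  expect_equal(edgeKeys(f), "a|pp|s")

  allZero <- attributeTable("Flux", c("a|pp|s" = 0, "b|pp|s" = 0))
  f0 <- suppressMessages(filterPositive(g, allZero))
  expect_equal(numEdges(f0), 0)

  thr <- attributeTable("Flux", c("a|pp|s" = 2.5, "b|pp|s" = 5))
  ft <- suppressMessages(filterPositive(g, thr, threshold = 3))
  expect_equal(edgeKeys(ft), "b|pp|s")
})

test_that("orphaned nodes are dropped unless kept by flag or positive node value", {
  g <- readSIF(text = c("s pp a", "s pp b", "lonely"))
  fluxes <- c("a|pp|s" = 1, "b|pp|s" = 0)
  f <- suppressMessages(filterPositive(g, fluxes))
  expect_setequal(nodeIds(f), c("a", "s", "lonely"))  # b orphaned; lonely untouched
  fk <- suppressMessages(filterPositive(g, fluxes, keepOrphans = TRUE))
  expect_setequal(nodeIds(fk), c("a", "b", "s", "lonely"))
  fv <- suppressMessages(filterPositive(g, c(fluxes, b = 9)))
  expect_setequal(nodeIds(fv), c("a", "b", "s", "lonely"))

  ## node-keyed table: induced subgraph on positive nodes
  nodeTab <- attributeTable("Flux", c(s = 1, a = 2, b = 0, lonely = 0))
  fn <- suppressMessages(filterPositive(g, nodeTab))
  expect_setequal(nodeIds(fn), c("a", "s"))
  expect_equal(edgeKeys(fn), "a|pp|s")
})

test_that("attribute splitting induces one subgraph per value and partitions nodes", {
  g <- netGraph(data.frame(
    from = c("a", "b", "c", "e"), to = c("b", "c", "d", "f"),
    interaction = "pp"))
  tab <- attributeTable("Filename",
                        c(a = "A", b = "A", c = "B", d = "B", e = "C"))
  groups <- splitByAttribute(g, tab)
  expect_equal(names(groups), c("A", "B", "C", "unassigned"))
  expect_setequal(nodeIds(groups$A), c("a", "b"))
  expect_equal(edgeKeys(groups$A), "a|pp|b")
  ## the cross-group edge b-c appears in no subgraph
  expect_false("b|pp|c" %in% unlist(lapply(groups, edgeKeys)))
  ## f has no attribute: lands in "unassigned"; groups partition the node set
  expect_setequal(nodeIds(groups$unassigned), "f")
  all <- unlist(lapply(groups, nodeIds))
  expect_setequal(all, nodeIds(g))
  expect_equal(length(all), numNodes(g))

  ## all nodes one value: single subgraph equal to the input
  one <- splitByAttribute(g, attributeTable("F", setNames(
    rep("only", numNodes(g)), nodeIds(g))))
  expect_length(one, 1)
  expect_identical(graphEdges(one$only), graphEdges(g))

  ## empty table: everything unassigned
  none <- splitByAttribute(g, attributeTable("F", setNames(character(), character())))
  expect_equal(names(none), "unassigned")
  expect_setequal(nodeIds(none$unassigned), nodeIds(g))
})

test_that("six distinct condition values give six subnetworks", {
  g <- randomGraph(24, 30, seed = 31)
  vals <- setNames(rep(paste0("cond", 1:6), each = 4), nodeIds(g))
  groups <- splitByAttribute(g, attributeTable("Filename", vals))
  expect_length(groups, 6)
})

test_that("motion events are consecutive set differences, deletions first", {
  fA <- netGraph(nodes = c("A", "B"))
  fB <- netGraph(nodes = c("B", "C"))
  mn <- buildMotionNetwork(list(fA, fB), c("f1", "f2"))
  ev2 <- mn@events[[2]]
  expect_equal(vapply(ev2, `[[`, character(1), "kind"), c("delete", "insert"))
  expect_equal(vapply(ev2, `[[`, character(1), "id"), c("A", "C"))

  ## identical consecutive frames produce no events
  same <- buildMotionNetwork(list(fA, fA), c("f1", "f2"))
  expect_length(same@events[[2]], 0)

  ## a node present in frames 1 and 3 only is deleted at 2, re-inserted at 3
  f1 <- netGraph(nodes = c("A", "B"))
  f2 <- netGraph(nodes = "B")
  f3 <- netGraph(nodes = c("A", "B"))
  mn3 <- buildMotionNetwork(list(f1, f2, f3))
  kinds2 <- vapply(mn3@events[[2]], function(e) paste(e$kind, e$id), character(1))
  kinds3 <- vapply(mn3@events[[3]], function(e) paste(e$kind, e$id), character(1))
  expect_equal(kinds2, "delete A")
  expect_equal(kinds3, "insert A")

  expect_error(buildMotionNetwork(list(fA, fB), c("x", "x")),
               class = "netscene3dConfigError")
})

test_that("replaying events from empty reproduces every frame exactly", {
  base <- randomGraph(15, 25, seed = 41)
  for (s in 1:5) {
    frames <- syntheticFrames(base, 4, churn = 0.4, seed = 500 + s)
    mn <- buildMotionNetwork(frames)
    for (t in seq_along(frames)) {
      rep_ <- replayMotion(mn, t)
      expect_identical(graphNodes(rep_), graphNodes(frames[[t]]))
      expect_identical(graphEdges(rep_), graphEdges(frames[[t]]))
    }
    ## union graph equals the union of all frames
    expect_setequal(nodeIds(mn@unionGraph),
                    unique(unlist(lapply(frames, nodeIds))))
    expect_setequal(edgeKeys(mn@unionGraph),
                    unique(unlist(lapply(frames, edgeKeys))))
  }
})

test_that("animation keeps a fixed union layout: shared nodes never move", {
  g <- randomGraph(12, 18, seed = 51)
  frames <- syntheticFrames(g, 3, churn = 0.3, seed = 52)
  mn <- buildMotionNetwork(frames)
  scenes <- animateMotion(mn, params = layoutParams(seed = 53))
  expect_length(scenes, 3)
  union <- multilevelLayout(mn@unionGraph, layoutParams(seed = 53))
  for (sc in scenes) {
    ids <- rownames(sc@layout@positions)
    expect_identical(sc@layout@positions, union@positions[ids, , drop = FALSE])
  }

  ## single-frame motion renders like the static scene
  mn1 <- buildMotionNetwork(list(g))
  sc1 <- animateMotion(mn1, params = layoutParams(seed = 53))[[1]]
  union1 <- multilevelLayout(mn1@unionGraph, layoutParams(seed = 53))
  expect_true(sceneIdentical(sc1, makeScene(mn1@unionGraph, union1)))
})

test_that("a six-condition animation runs end-to-end and replays its inputs", {
  g <- randomGraph(20, 32, seed = 61)
  frames <- syntheticFrames(g, 6, churn = 0.25, seed = 62)
  ts <- syntheticTimecourse(g, 6, seed = 63)
  mn <- buildMotionNetwork(frames)
  scenes <- animateMotion(mn, params = layoutParams(seed = 64),
                          timeseries = ts, map = "size")
  expect_length(scenes, 6)
  for (t in 1:6) {
    expect_setequal(nodeIds(scenes[[t]]@graph), nodeIds(frames[[t]]))
    expect_setequal(edgeKeys(scenes[[t]]@graph), edgeKeys(frames[[t]]))
  }
  ## the style channel actually varies with the data
  expect_gt(length(unique(unlist(lapply(scenes, slot, "nodeSize")))), 1)

  ## an explicit style for an absent element names frame and element
  bad <- list(list(nodeSize = c(zz = 10)))
  mn1 <- buildMotionNetwork(list(g))
  expect_error(animateMotion(mn1, params = layoutParams(seed = 64),
                             perFrameStyles = bad),
               "zz", class = "netscene3dLookupError")
})
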