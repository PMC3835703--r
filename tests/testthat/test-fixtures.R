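test_that("random graphs are uniform simple graphs, deterministic per seed", {
  expect_equal(numNodes(randomGraph(1, 0, seed = 1)), 1)
  expect_identical(randomGraph(10, 15, seed = 1), randomGraph(10, 15, seed = 1))
  expect_false(identical(randomGraph(10, 15, seed = 1),
                         randomGraph(10, 15, seed = 2)))
  full <- randomGraph(10, 45, seed = 3)
  expect_equal(numEdges(full), 45)
  expect_error(randomGraph(10, 46, seed = 1),
               class = "netscene3dParameterError")
  ## simple: no self-loops, no duplicate pairs
  e <- graphEdges(randomGraph(30, 60, seed = 4))
  expect_true(all(e$from != e$to))
  expect_equal(anyDuplicated(paste(e$from, e$to)), 0)
})

test_that("synthetic assemblies are valid LastGraphs whose implants are recovered", {
  clean <- syntheticAssembly(20, 0, seed = 5)
  g0 <- assemblyToGraph(readLastGraph(text = clean))
  expect_equal(nrow(detectBubbles(g0)), 0)

  txt <- syntheticAssembly(30, 3, seed = 6)
  asm <- readLastGraph(text = txt)
  expect_equal(nrow(asm@nodes), 30)
  g <- assemblyToGraph(asm)
  expect_equal(nrow(detectBubbles(g)), 3)

  expect_identical(syntheticAssembly(30, 3, seed = 6), txt)
  expect_error(syntheticAssembly(8, 3, seed = 1),
               class = "netscene3dParameterError")
})

test_that("synthetic time courses have one value per node per frame", {
  g <- randomGraph(7, 9, seed = 7)
  ts <- syntheticTimecourse(g, 5, seed = 8)
  expect_equal(dim(ts@values), c(7, 5))
  expect_setequal(rownames(ts@values), nodeIds(g))
  expect_true(all(ts@values > 0))   # log-normal surrogate is positive
  expect_identical(syntheticTimecourse(g, 5, seed = 8), ts)
})

test_that("zero churn gives identical frames and an eventless motion tail", {
  g <- randomGraph(10, 14, seed = 9)
  frames <- syntheticFrames(g, 4, churn = 0, seed = 10)
  for (f in frames) expect_identical(graphEdges(f), graphEdges(g))
  mn <- buildMotionNetwork(frames)
  expect_true(all(lengths(mn@events[-1]) == 0))

  churned <- syntheticFrames(g, 4, churn = 0.5, seed = 11)
  expect_true(all(vapply(churned, numNodes, numeric(1)) == 5))
  expect_error(syntheticFrames(g, 4, churn = 2, seed = 1),
               class = "netscene3dParameterError")
})
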