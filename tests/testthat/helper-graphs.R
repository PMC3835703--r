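## Small graph builders used across the suite.

pathGraph <- function(n, prefix = "p") {
  ids <- sprintf(paste0(prefix, "%02d"), seq_len(n))
  netGraph(data.frame(from = ids[-n], to = ids[-1], interaction = "pp"),
           nodes = ids)
}

ringGraph <- function(n, prefix = "r") {
  ids <- sprintf(paste0(prefix, "%02d"), seq_len(n))
  netGraph(data.frame(from = ids, to = ids[c(2:n, 1)], interaction = "pp"))
}

triangleGraph <- function() {
  readSIF(text = c("a pp b", "b pp c", "a pp c"))
}

## the minimal bubble: two parallel two-edge paths s..t
diamondGraph <- function() {
  readSIF(text = c("s pp a", "a pp t", "s pp b", "b pp t"))
}

sceneFor <- function(graph, seed = 1, ...) {
  makeScene(graph, frLayout(graph, layoutParams(seed = seed)), ...)
}
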