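## Independent brute-force oracles. These re-derive expected results with
## the plainest possible code (double loops, exhaustive recursion) and stay
## independent of the implementation paths they check.

## Direct double-loop Fruchterman-Reingold force summation in 3D:
## repulsion k^2/d on every pair, attraction d^2/k on every edge.
bruteForceDisplacements <- function(positions, edges, k) {
  n <- nrow(positions)
  disp <- matrix(0, n, 3, dimnames = dimnames(positions))
  ids <- rownames(positions)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      delta <- positions[i, ] - positions[j, ]
      d <- sqrt(sum(delta^2))
      disp[i, ] <- disp[i, ] + delta / d * (k^2 / d)
    }
  }
  for (r in seq_len(nrow(edges))) {
    a <- match(edges$from[r], ids); b <- match(edges$to[r], ids)
    if (a == b) next
    delta <- positions[a, ] - positions[b, ]
    d <- sqrt(sum(delta^2))
    f <- d^2 / k
    disp[a, ] <- disp[a, ] - delta / d * f
    disp[b, ] <- disp[b, ] + delta / d * f
  }
  disp
}

## plain adjacency (self-loops dropped), independent of the package internals
oracleAdjacency <- function(graph) {
  e <- graphEdges(graph)
  ids <- sort(nodeIds(graph), method = "radix")
  adj <- setNames(lapply(ids, function(x) character()), ids)
  for (r in seq_len(nrow(e))) {
    a <- e$from[r]; b <- e$to[r]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  lapply(adj, sort, method = "radix")
}

## exhaustive recursive enumeration of all simple u-v paths with edge length
## in [2, maxLen]
oracleSimplePaths <- function(adj, u, v, maxLen) {
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == v) {
      if (length(path) >= 3L) out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= maxLen) return(invisible())
    for (w in adj[[cur]]) {
      if (!w %in% path) walk(c(path, w))
    }
    invisible()
  }
  walk(u)
  out
}

## the shared bubble definition, computed from exhaustively enumerated paths:
## >= 2 internally disjoint paths (greedy maximal set in canonical order),
## one bubble per spanned node set, represented by the highest-degree pair
oracleBubbles <- function(graph, maxLen) {
  adj <- oracleAdjacency(graph)
  ids <- names(adj)
  deg <- lengths(adj)
  cand <- list()
  for (ui in seq_along(ids)) {
    for (vi in seq_along(ids)) {
      if (vi <= ui) next
      u <- ids[ui]; v <- ids[vi]
      if (deg[[u]] < 2L || deg[[v]] < 2L) next
      paths <- oracleSimplePaths(adj, u, v, maxLen)
      if (length(paths) < 2L) next
      ## canonical order: by length then joined id string
      o <- order(lengths(paths),
                 vapply(paths, paste, character(1), collapse = "\r"),
                 method = "radix")
      sel <- list(); used <- character()
      for (p in paths[o]) {
        interior <- p[-c(1L, length(p))]
        if (!any(interior %in% used)) {
          sel[[length(sel) + 1L]] <- p
          used <- c(used, interior)
        }
      }
      if (length(sel) < 2L) next
      cand[[length(cand) + 1L]] <- list(
        source = u, sink = v, n = length(sel),
        key = paste(sort(unique(unlist(sel)), method = "radix"),
                    collapse = "\r"),
        degSum = deg[[u]] + deg[[v]],
        ui = ui, vi = vi)
    }
  }
  if (!length(cand)) {
    return(data.frame(source = character(), sink = character(),
                      nPaths = integer()))
  }
  keys <- vapply(cand, `[[`, character(1), "key")
  degs <- vapply(cand, `[[`, numeric(1), "degSum")
  uis <- vapply(cand, `[[`, numeric(1), "ui")
  vis <- vapply(cand, `[[`, numeric(1), "vi")
  best <- order(-degs, uis, vis)
  pick <- best[!duplicated(keys[best])]
  pick <- pick[order(uis[pick], vis[pick])]
  data.frame(source = vapply(cand[pick], `[[`, character(1), "source"),
             sink = vapply(cand[pick], `[[`, character(1), "sink"),
             nPaths = vapply(cand[pick], `[[`, integer(1), "n"),
             stringsAsFactors = FALSE)
}
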