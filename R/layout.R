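## 3D force-directed layout: single-level Fruchterman-Reingold embedder and
## the multilevel coarsen/prolong/refine scheme for large graphs.

#' Layout parameters
#'
#' The spring embedder balances pairwise repulsion (magnitude `k^2/d`)
#' against attraction along edges (magnitude `d^2/k`), with per-iteration
#' displacements capped at a geometrically cooled temperature. The ideal
#' edge length is `k = C * (volume / n)^(1/3)`; with the defaults
#' (`C = 1`, `volume = n`) `k = 1`, so all layout lengths are expressed in
#' units of the ideal edge length.
#'
#' @param C positive scale constant of the ideal length.
#' @param volume layout volume; default `NULL` means `n` (one unit cell per
#'   node), giving `k = C`.
#' @param iterations force iterations per level.
#' @param coolingFactor geometric cooling factor in (0, 1).
#' @param initialTemperature displacement cap at iteration 1; default `NULL`
#'   means `0.1 * k * n^(1/3)` (a tenth of the layout radius).
#' @param neighborhood `"all-pairs"` for exact repulsion, or a positive
#'   radius: only pairs closer than the radius repel. [multilevelLayout()]
#'   refines with a radius of `2k` unless a numeric radius is given here.
#' @param maxPartners with a finite neighborhood, the deterministic per-node
#'   budget of repulsion partners (nearest grid cells first); bounds
#'   per-iteration repulsive force evaluations by `maxPartners * n`.
#' @param coarsestSize multilevel recursion stops at this node count; graphs
#'   at or below it are laid out single-level, so toy graphs bypass
#'   coarsening entirely.
#' @param jitterRadius prolongation offset radius; default `NULL` means `k/4`.
#' @param seed integer seed; every random draw in the layout derives from it,
#'   making layouts bit-for-bit reproducible.
#' @return a list of class `layoutParams`.
#' @export
layoutParams <- function(C = 1, volume = NULL, iterations = 50,
                         coolingFactor = 0.95, initialTemperature = NULL,
                         neighborhood = "all-pairs", maxPartners = 40,
                         coarsestSize = 50, jitterRadius = NULL, seed = 42) {
  if (C <= 0) paramError("C must be positive")
  if (!is.null(volume) && volume <= 0) paramError("volume must be positive")
  if (iterations < 1) paramError("iterations must be a positive integer")
  if (coolingFactor <= 0 || coolingFactor >= 1) {
    paramError("cooling factor must lie in (0, 1)")
  }
  if (!identical(neighborhood, "all-pairs") &&
      (!is.numeric(neighborhood) || neighborhood <= 0)) {
    paramError("neighborhood must be \"all-pairs\" or a positive radius")
  }
  structure(list(C = C, volume = volume, iterations = as.integer(iterations),
                 coolingFactor = coolingFactor,
                 initialTemperature = initialTemperature,
                 neighborhood = neighborhood,
                 maxPartners = as.integer(maxPartners),
                 coarsestSize = as.integer(coarsestSize),
                 jitterRadius = jitterRadius,
                 seed = as.integer(seed)),
            class = "layoutParams")
}

## Fill in the n-dependent derived quantities.
resolveParams <- function(params, n) {
  p <- unclass(params)
  if (is.null(p$volume)) p$volume <- n
  p$k <- p$C * (p$volume / n)^(1 / 3)
  if (is.null(p$initialTemperature)) {
    p$initialTemperature <- 0.1 * p$k * n^(1 / 3)
  }
  if (is.null(p$jitterRadius)) p$jitterRadius <- p$k / 4
  p$n <- n
  p
}

## id -> 0-based index edge matrix for the C++ kernel
edgeIndexMatrix <- function(edges, ids) {
  if (!nrow(edges)) return(matrix(integer(), ncol = 2))
  cbind(match(edges$from, ids), match(edges$to, ids)) - 1L
}

checkFinitePositions <- function(positions) {
  bad <- rownames(positions)[!is.finite(rowSums(positions))]
  if (length(bad)) {
    numericError("non-finite coordinate(s) for node(s): %s",
                 paste(head(bad, 5), collapse = ", "))
  }
}

## deterministic de-coincidence jitter (no RNG: index-derived directions)
jitterCoincident <- function(positions, k) {
  key <- paste(positions[, 1], positions[, 2], positions[, 3])
  dup <- which(duplicated(key))
  for (i in dup) {
    positions[i, ] <- positions[i, ] +
      1e-6 * k * c(sin(i), cos(i), sin(2 * i + 1))
  }
  positions
}

#' One force pass: displacements for all nodes
#'
#' Computes the Fruchterman-Reingold displacement of every node for the
#' current positions: repulsion `k^2/d` between node pairs within the
#' repulsion neighborhood, attraction `d^2/k` along each edge, force sums
#' capped at `temperature`. Exactly coincident nodes are jittered apart
#' (deterministically) before evaluation. The returned counts feed the
#' layout's force-evaluation accounting.
#'
#' @param positions numeric n x 3 matrix with node ids as rownames.
#' @param edges a [NetGraph-class] or a data.frame with `from`/`to` columns;
#'   all endpoints must be positioned.
#' @param params a [layoutParams()] list.
#' @param temperature displacement cap; `Inf` disables capping. Default: the
#'   resolved initial temperature.
#' @return list with `displacements` (n x 3, same rownames),
#'   `repulsionEvals` and `attractionEvals`.
#' @export
computeDisplacements <- function(positions, edges, params = layoutParams(),
                                 temperature = NULL) {
  if (is(edges, "NetGraph")) edges <- edges@edges
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  ids <- rownames(positions)
  if (is.null(ids)) paramError("positions must have node ids as rownames")
  checkFinitePositions(positions)
  miss <- setdiff(c(edges$from, edges$to), ids)
  if (length(miss)) {
    lookupError("edge endpoint(s) not positioned: %s",
                paste(head(miss, 5), collapse = ", "))
  }
  p <- resolveParams(params, nrow(positions))
  if (is.null(temperature)) temperature <- p$initialTemperature
  cutoff <- if (identical(p$neighborhood, "all-pairs")) -1 else p$neighborhood
  positions <- jitterCoincident(positions, p$k)
  res <- .frDisplacements(positions, edgeIndexMatrix(edges, ids),
                          p$k, temperature, cutoff, p$maxPartners)
  disp <- res$displacements
  rownames(disp) <- ids
  colnames(disp) <- c("x", "y", "z")
  list(displacements = disp,
       repulsionEvals = res$repulsionEvals,
       attractionEvals = res$attractionEvals)
}

## Iterate force passes with geometric cooling from given start positions.
refineLayout <- function(graph, positions, p, cutoff, levelLabel) {
  edges <- edgeIndexMatrix(graph@edges, rownames(positions))
  temp <- p$initialTemperature
  repTotal <- 0
  log <- vector("list", p$iterations)
  for (it in seq_len(p$iterations)) {
    res <- .frDisplacements(positions, edges, p$k, temp, cutoff, p$maxPartners)
    positions <- positions + res$displacements
    repTotal <- repTotal + res$repulsionEvals
    log[[it]] <- data.frame(level = levelLabel, iteration = it,
                            repulsionEvals = res$repulsionEvals,
                            attractionEvals = res$attractionEvals)
    temp <- temp * p$coolingFactor
  }
  positions <- sweep(positions, 2, colMeans(positions))
  list(positions = positions, evals = repTotal, log = do.call(rbind, log))
}

## seeded initial placement inside a ball of radius k * n^(1/3)
initialPositions <- function(ids, p) {
  n <- length(ids)
  withSeed(subSeed(p$seed, 0), {
    dir <- matrix(stats::rnorm(3 * n), ncol = 3)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    r <- p$k * n^(1 / 3) * runif(n)^(1 / 3)
    pos <- dir * r
  })
  dimnames(pos) <- list(ids, c("x", "y", "z"))
  jitterCoincident(pos, p$k)
}

#' Single-level 3D force-directed layout
#'
#' The baseline spring embedder: seeded random initial positions in a ball
#' of radius `k * n^(1/3)`, then `iterations` force passes with geometric
#' cooling. Exact all-pairs repulsion by default (quadratic per iteration;
#' see [multilevelLayout()] for large graphs). Deterministic for a fixed
#' seed; the final layout is centred on the origin, so a single node sits
#' exactly at the origin.
#'
#' @param graph a non-empty [NetGraph-class].
#' @param params a [layoutParams()] list.
#' @return a [LayoutState-class].
#' @examples
#' g <- readSIF(text = "A pp B")
#' st <- frLayout(g, layoutParams(seed = 1))
#' layoutQuality(g, st)
#' @export
frLayout <- function(graph, params = layoutParams()) {
  stopifnot(is(graph, "NetGraph"))
  n <- numNodes(graph)
  if (n == 0) paramError("cannot lay out an empty graph")
  p <- resolveParams(params, n)
  pos <- initialPositions(graph@nodes$id, p)
  cutoff <- if (identical(p$neighborhood, "all-pairs")) -1 else p$neighborhood
  ref <- refineLayout(graph, pos, p, cutoff, levelLabel = n)
  new("LayoutState", positions = ref$positions, params = p,
      forceEvaluations = ref$evals, evalLog = ref$log)
}

#' Coarsen a graph by greedy maximal matching
#'
#' Visits edges in a seeded-random order (or id-sorted order), greedily
#' matching endpoint pairs whose nodes are both unmatched. Each matched pair
#' collapses to a supernode named after its lexicographically smaller member;
#' unmatched nodes pass through under their own id. Self-loops arising from
#' collapse are removed and parallel coarse edges merge with summed `weight`
#' (fine edges count 1 unless they already carry a weight). On any graph
#' with at least one non-loop edge the coarse node count strictly decreases.
#'
#' @param graph a [NetGraph-class] with at least 2 nodes.
#' @param seed seed for the edge visiting order.
#' @param edgeOrder `"random"` (seeded permutation) or `"sorted"`
#'   (id-sorted edge order, useful for hand-traceable examples).
#' @return a [CoarseningLevel-class].
#' @export
coarsenGraph <- function(graph, seed = 1, edgeOrder = c("random", "sorted")) {
  stopifnot(is(graph, "NetGraph"))
  edgeOrder <- match.arg(edgeOrder)
  ids <- graph@nodes$id   # sorted; index order == id order
  if (length(ids) < 2) paramError("coarsening needs at least 2 nodes")
  e <- graph@edges
  keep <- e$from != e$to
  ai <- match(e$from[keep], ids)
  bi <- match(e$to[keep], ids)
  w <- if ("weight" %in% names(e)) as.numeric(e$weight[keep]) else rep(1, sum(keep))
  w[is.na(w)] <- 1
  ord <- seq_along(ai)
  if (edgeOrder == "random" && length(ord) > 1) {
    ord <- withSeed(seed, sample(ord))
  }
  par <- seq_along(ids)
  matched <- logical(length(ids))
  for (i in ord) {
    a <- ai[i]; b <- bi[i]
    if (!matched[a] && !matched[b]) {
      rep_ <- min(a, b)          # ids sorted => smaller index = smaller id
      par[a] <- rep_; par[b] <- rep_
      matched[a] <- matched[b] <- TRUE
    }
  }
  parentIds <- ids[par]
  coarseNodeIds <- idSort(unique(parentIds))

  cf <- parentIds[ai]; ct <- parentIds[bi]
  keep2 <- cf != ct
  cf <- cf[keep2]; ct <- ct[keep2]; cw <- w[keep2]
  coarseEdges <- NULL
  if (length(cf)) {
    swap <- rankOf(cf, ct) > rankOf(ct, cf)
    tmp <- cf[swap]; cf[swap] <- ct[swap]; ct[swap] <- tmp
    key <- paste(cf, ct, sep = "\r")
    agg <- rowsum(cw, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    coarseEdges <- data.frame(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      interaction = "link",
      weight = as.numeric(agg),
      stringsAsFactors = FALSE)
  }
  coarse <- netGraph(edges = coarseEdges, nodes = coarseNodeIds,
                     directed = FALSE)
  new("CoarseningLevel", coarseGraph = coarse,
      parentMap = setNames(parentIds, ids))
}

#' Prolong coarse positions to the fine graph
#'
#' Places every fine node at its supernode's position plus a seeded-random
#' offset of norm at most `jitterRadius`, so matched siblings start close
#' together (within `2 * jitterRadius`) but never exactly coincide.
#'
#' @param level a [CoarseningLevel-class].
#' @param coarseLayout a [LayoutState-class] (or bare position matrix)
#'   covering the coarse graph.
#' @param jitterRadius maximum offset norm.
#' @param seed seed for the offsets.
#' @return position matrix for the fine graph (fine ids as rownames).
#' @export
prolongPositions <- function(level, coarseLayout, jitterRadius, seed = 1) {
  stopifnot(is(level, "CoarseningLevel"))
  cpos <- if (is(coarseLayout, "LayoutState")) coarseLayout@positions else coarseLayout
  fineIds <- idSort(names(level@parentMap))
  parents <- level@parentMap[fineIds]
  miss <- setdiff(unique(parents), rownames(cpos))
  if (length(miss)) {
    lookupError("no coarse position for supernode(s): %s",
                paste(head(miss, 5), collapse = ", "))
  }
  n <- length(fineIds)
  withSeed(seed, {
    dir <- matrix(stats::rnorm(3 * n), ncol = 3)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    off <- dir * (jitterRadius * runif(n)^(1 / 3))
  })
  pos <- cpos[parents, , drop = FALSE] + off
  dimnames(pos) <- list(fineIds, c("x", "y", "z"))
  jitterCoincident(pos, jitterRadius)
}

#' Multilevel 3D layout
#'
#' Recursively coarsens the graph by greedy matching until at most
#' `coarsestSize` nodes remain (or no further progress is possible), lays
#' out the coarsest graph with the exact single-level embedder, then
#' prolongs positions back level by level, refining each level with
#' neighborhood-limited repulsion (radius `2k` on a uniform grid with a
#' deterministic per-node partner budget). Per-iteration repulsive force
#' evaluations are thus bounded by `maxPartners * n` instead of growing as
#' `n^2/2`. Graphs already at or below `coarsestSize` are laid out exactly
#' like [frLayout()] with the same seed. Deterministic for a fixed seed.
#'
#' @param graph a non-empty [NetGraph-class].
#' @param params a [layoutParams()] list.
#' @return a [LayoutState-class]; `@evalLog` has one row per (level,
#'   iteration) with the evaluation counts.
#' @export
multilevelLayout <- function(graph, params = layoutParams()) {
  stopifnot(is(graph, "NetGraph"))
  n <- numNodes(graph)
  if (n == 0) paramError("cannot lay out an empty graph")
  if (n <= params$coarsestSize) return(frLayout(graph, params))

  levels <- list()
  g <- graph
  while (numNodes(g) > params$coarsestSize) {
    cl <- coarsenGraph(g, seed = subSeed(params$seed, 100 + length(levels)))
    if (numNodes(cl@coarseGraph) >= numNodes(g)) break
    levels[[length(levels) + 1L]] <- list(fine = g, cl = cl)
    g <- cl@coarseGraph
  }

  state <- frLayout(g, params)
  pos <- state@positions
  log <- state@evalLog
  evals <- state@forceEvaluations

  for (li in rev(seq_along(levels))) {
    fine <- levels[[li]]$fine
    cl <- levels[[li]]$cl
    p <- resolveParams(params, numNodes(fine))
    pos <- prolongPositions(cl, pos, jitterRadius = p$jitterRadius,
                            seed = subSeed(params$seed, 200 + li))
    cutoff <- if (is.numeric(params$neighborhood)) params$neighborhood else 2 * p$k
    ref <- refineLayout(fine, pos, p, cutoff, levelLabel = numNodes(fine))
    pos <- ref$positions
    log <- rbind(log, ref$log)
    evals <- evals + ref$evals
  }

  new("LayoutState", positions = pos,
      params = resolveParams(params, n),
      forceEvaluations = evals, evalLog = log)
}

#' Layout quality metrics
#'
#' @param graph a [NetGraph-class].
#' @param layout a [LayoutState-class] covering the graph.
#' @return list with `edgeLengthMean`, `edgeLengthCV` (coefficient of
#'   variation, 0 when fewer than 2 edges) and `minSeparation` (minimum
#'   pairwise node distance; `Inf` for fewer than 2 nodes).
#' @export
layoutQuality <- function(graph, layout) {
  stopifnot(is(graph, "NetGraph"), is(layout, "LayoutState"))
  pos <- layout@positions
  miss <- setdiff(graph@nodes$id, rownames(pos))
  if (length(miss)) {
    lookupError("layout does not cover node(s): %s",
                paste(head(miss, 5), collapse = ", "))
  }
  e <- graph@edges[graph@edges$from != graph@edges$to, , drop = FALSE]
  lens <- numeric()
  if (nrow(e)) {
    d <- pos[e$from, , drop = FALSE] - pos[e$to, , drop = FALSE]
    lens <- sqrt(rowSums(d^2))
  }
  cv <- if (length(lens) >= 2 && mean(lens) > 0) stats::sd(lens) / mean(lens) else 0
  list(edgeLengthMean = if (length(lens)) mean(lens) else NA_real_,
       edgeLengthCV = cv,
       minSeparation = .minSeparation(pos[graph@nodes$id, , drop = FALSE]))
}

setMethod("show", "LayoutState", function(object) {
  cat(sprintf("LayoutState: %d nodes, %g repulsive force evaluations\n",
              nrow(object@positions), object@forceEvaluations))
  invisible(object)
})
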