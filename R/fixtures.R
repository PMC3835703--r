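## Seeded synthetic-data generators: random graphs, assemblies with
## implanted bubbles, time courses and presence/absence frame series. Every
## generator is a pure function of its parameters and seed.

#' Seeded uniform random graph
#'
#' Draws a simple undirected graph with `n` nodes and `m` edges uniformly
#' from all such graphs (edge set sampled without replacement from the
#' `n(n-1)/2` possible pairs). Node ids are zero-padded (`v01`, `v02`, ...)
#' so lexicographic and numeric order agree.
#'
#' @param n number of nodes (>= 1).
#' @param m number of edges, `0 <= m <= n(n-1)/2`.
#' @param seed integer seed; identical parameters give identical graphs.
#' @param interaction interaction label for all edges.
#' @return a [NetGraph-class].
#' @export
randomGraph <- function(n, m, seed = 1, interaction = "pp") {
  if (n < 1) paramError("n must be >= 1")
  maxM <- n * (n - 1) / 2
  if (m < 0 || m > maxM) {
    paramError("m must lie in [0, %d] for n = %d", maxM, n)
  }
  width <- max(2L, nchar(as.character(n)))
  ids <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  edges <- NULL
  if (m > 0) {
    pick <- withSeed(seed, sample(maxM, m))
    ## decode linear index over the strictly-lower-triangular pair table
    j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)   # larger endpoint (2..n)
    i <- pick - (j - 1) * (j - 2) / 2            # smaller endpoint (1..j-1)
    ## guard against floating-point slips at triangular boundaries
    hi <- i > j - 1
    i[hi] <- i[hi] - (j[hi] - 1); j[hi] <- j[hi] + 1
    lo <- i < 1
    j[lo] <- j[lo] - 1; i[lo] <- pick[lo] - (j[lo] - 1) * (j[lo] - 2) / 2
    edges <- data.frame(from = ids[i], to = ids[j],
                        interaction = interaction, stringsAsFactors = FALSE)
  }
  netGraph(edges = edges, nodes = ids, directed = FALSE)
}

#' Synthetic Velvet assembly with implanted bubbles
#'
#' Emits a format-valid LastGraph whose folded network contains exactly
#' `nBubbles` bubbles: a backbone contig path in which `nBubbles` randomly
#' chosen edges are each replaced by a two-arm diamond (two parallel
#' single-node paths), plus dangling decoy branches that fork off the
#' backbone without reconverging. Node ids are randomly permuted, arc
#' orientation signs are random (folding removes them), multiplicities,
#' lengths and coverages are drawn from plausible short-read ranges, and the
#' two sequence lines per node are random DNA.
#'
#' @param nNodes total node count; must allow `2 * nBubbles` arm nodes, a
#'   backbone of at least `nBubbles + 1` nodes and the decoys.
#' @param nBubbles number of implanted diamonds (>= 0).
#' @param seed integer seed.
#' @param nDecoys dangling decoy nodes (default up to 3, as `nNodes` allows).
#' @param hashLength k-mer length written to the header.
#' @return character vector: the LastGraph lines (parseable by
#'   [readLastGraph()]).
#' @export
syntheticAssembly <- function(nNodes, nBubbles, seed = 1, nDecoys = NULL,
                              hashLength = 21) {
  if (nBubbles < 0) paramError("nBubbles must be >= 0")
  if (is.null(nDecoys)) {
    nDecoys <- max(0L, min(3L, nNodes - (3L * nBubbles + 2L)))
  }
  backboneLen <- nNodes - 2L * nBubbles - nDecoys
  if (backboneLen < max(2L, nBubbles + 1L)) {
    paramError("nNodes = %d too small for %d bubbles and %d decoys",
               nNodes, nBubbles, nDecoys)
  }
  withSeed(seed, {
    perm <- sample(nNodes)                 # random id assignment
    backbone <- perm[seq_len(backboneLen)]
    armPool <- perm[backboneLen + seq_len(2L * nBubbles)]
    decoys <- perm[backboneLen + 2L * nBubbles + seq_len(nDecoys)]

    arcs <- data.frame(from = integer(), to = integer())
    bubbleEdges <- if (nBubbles > 0) {
      sort(sample(backboneLen - 1L, nBubbles))
    } else integer()
    for (i in seq_len(backboneLen - 1L)) {
      a <- backbone[i]; b <- backbone[i + 1L]
      if (i %in% bubbleEdges) {
        w <- which(bubbleEdges == i)
        arm1 <- armPool[2L * w - 1L]; arm2 <- armPool[2L * w]
        arcs <- rbind(arcs,
                      data.frame(from = c(a, arm1, a, arm2),
                                 to = c(arm1, b, arm2, b)))
      } else {
        arcs <- rbind(arcs, data.frame(from = a, to = b))
      }
    }
    for (d in decoys) {
      at <- backbone[sample(backboneLen, 1L)]
      arcs <- rbind(arcs, data.frame(from = at, to = d))
    }

    signs <- matrix(sample(c(-1L, 1L), 2L * nrow(arcs), replace = TRUE),
                    ncol = 2)
    arcLines <- sprintf("ARC\t%d\t%d\t%d",
                        arcs$from * signs[, 1], arcs$to * signs[, 2],
                        sample(1:20, nrow(arcs), replace = TRUE))

    lens <- sample(5:60, nNodes, replace = TRUE)
    cov1 <- round(runif(nNodes, 50, 3000))
    cov2 <- round(runif(nNodes, 0, 300))
    nodeLines <- character()
    for (id in sort(perm)) {
      l <- lens[id]
      sq1 <- paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                   collapse = "")
      sq2 <- paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                   collapse = "")
      nodeLines <- c(nodeLines,
                     sprintf("NODE\t%d\t%d\t%d\t%d", id, l, cov1[id], cov2[id]),
                     sq1, sq2)
    }
    header <- sprintf("%d\t%d\t%d\t1", nNodes, nNodes * 10L, hashLength)
    c(header, nodeLines, arcLines)
  })
}

#' Synthetic log-normal time course
#'
#' Per-node values drawn independently per frame from a log-normal
#' distribution (positive and right-skewed, as expression intensities and
#' metabolic fluxes are).
#'
#' @param graph the [NetGraph-class] whose nodes get values.
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters.
#' @return a [TimeSeriesTable-class] with frame labels `t1`, `t2`, ...
#' @export
syntheticTimecourse <- function(graph, nFrames, seed = 1,
                                meanlog = 0, sdlog = 1) {
  stopifnot(is(graph, "NetGraph"))
  if (nFrames < 1) paramError("nFrames must be >= 1")
  ids <- graph@nodes$id
  vals <- withSeed(seed, {
    matrix(rlnorm(length(ids) * nFrames, meanlog, sdlog),
           nrow = length(ids), ncol = nFrames)
  })
  dimnames(vals) <- list(ids, paste0("t", seq_len(nFrames)))
  new("TimeSeriesTable", frameLabels = colnames(vals), values = vals)
}

#' Synthetic presence/absence frame series
#'
#' Generates an ordered series of frames by hiding, in each frame
#' independently, a random `churn` fraction of the graph's nodes (with
#' their incident edges) — the presence/absence pattern of per-condition
#' molecular networks. `churn = 0` leaves every frame identical to the
#' input graph.
#'
#' @param graph the union [NetGraph-class].
#' @param nFrames number of frames (>= 1).
#' @param churn fraction of nodes hidden per frame, in `[0, 1]`.
#' @param seed integer seed.
#' @return list of [NetGraph-class] frames (length `nFrames`).
#' @export
syntheticFrames <- function(graph, nFrames, churn = 0.3, seed = 1) {
  stopifnot(is(graph, "NetGraph"))
  if (nFrames < 1) paramError("nFrames must be >= 1")
  if (churn < 0 || churn > 1) paramError("churn must lie in [0, 1]")
  ids <- graph@nodes$id
  nHide <- round(churn * length(ids))
  withSeed(seed, {
    lapply(seq_len(nFrames), function(t) {
      keep <- if (nHide > 0) setdiff(ids, sample(ids, nHide)) else ids
      inducedSubgraph(graph, keep)
    })
  })
}
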