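## Time-course visual mapping, flux filtering, attribute splitting and
## motion networks.

checkFiniteValues <- function(values) {
  if (!is.numeric(values)) paramError("values must be numeric")
  bad <- names(values)[!is.finite(values)]
  if (is.null(names(values))) paramError("values must be named by element id")
  if (length(bad)) {
    numericError("non-finite value(s) for element(s): %s",
                 paste(head(bad, 5), collapse = ", "))
  }
}

## affine map of the observed value range onto [lo, hi]; constant input maps
## to the midpoint
affineMap <- function(values, range) {
  lo <- range[1]; hi <- range[2]
  vmin <- min(values); vmax <- max(values)
  if (vmax == vmin) return(setNames(rep((lo + hi) / 2, length(values)),
                                    names(values)))
  setNames(lo + (values - vmin) / (vmax - vmin) * (hi - lo), names(values))
}

#' Map numeric values to node sizes / edge thicknesses
#'
#' Affine map of `[min(values), max(values)]` onto the style's size (or
#' thickness) range, so the smallest value gets the minimum size and the
#' largest the maximum; order is preserved. Constant input maps every
#' element to the midpoint of the range (any choice is defensible; the
#' midpoint avoids degenerate invisible elements). Non-finite values are an
#' error naming the element.
#'
#' @param values named numeric vector (element id -> value).
#' @param style a [VisualStyle-class], or a bare numeric `c(min, max)`.
#' @return named numeric vector of sizes (thicknesses).
#' @examples
#' mapValuesToSize(c(a = 0, b = 1), visualStyle(sizeRange = c(10, 40)))
#' @export
mapValuesToSize <- function(values, style = visualStyle()) {
  checkFiniteValues(values)
  rng <- if (is(style, "VisualStyle")) style@sizeRange else as.numeric(style)
  affineMap(values, rng)
}

#' @rdname mapValuesToSize
#' @export
mapValuesToThickness <- function(values, style = visualStyle()) {
  checkFiniteValues(values)
  rng <- if (is(style, "VisualStyle")) style@thicknessRange else as.numeric(style)
  affineMap(values, rng)
}

#' Map numeric values to colours
#'
#' Linear interpolation across a three-anchor ramp (low, mid, high) anchored
#' at the minimum, midpoint and maximum of the value range. The default
#' `"heatmap"` scheme is the blue -> black -> yellow expression heat-map
#' convention; a user-defined scheme is three colour anchors.
#'
#' @param values named numeric vector.
#' @param scheme a scheme name (`"heatmap"`), a character vector of three
#'   colour anchors, or a [VisualStyle-class].
#' @return named character vector of `#RRGGBB` colours.
#' @export
mapValuesToColor <- function(values, scheme = "heatmap") {
  checkFiniteValues(values)
  ramp <- if (is(scheme, "VisualStyle")) {
    scheme@ramp
  } else if (is.character(scheme) && length(scheme) == 1L) {
    resolveRamp(scheme)
  } else if (is.character(scheme) && length(scheme) == 3L) {
    scheme
  } else {
    configError("colour scheme must be a scheme name, 3 anchors, or a VisualStyle")
  }
  vmin <- min(values); vmax <- max(values)
  t <- if (vmax == vmin) rep(0.5, length(values)) else (values - vmin) / (vmax - vmin)
  rgbVals <- grDevices::colorRamp(ramp, space = "rgb")(t)
  setNames(grDevices::rgb(rgbVals[, 1], rgbVals[, 2], rgbVals[, 3],
                          maxColorValue = 255),
           names(values))
}

#' Filter a network to elements with positive values
#'
#' Retains exactly the elements whose attribute value is strictly greater
#' than `threshold` (default 0, the "show only flux greater than zero"
#' filter for flux distributions). The table may cover edges (by edge key)
#' or nodes (by id); elements missing from the table are treated as 0 and
#' dropped, with a message reporting how many. When edges are filtered,
#' nodes orphaned by edge removal are kept only if they carry a positive
#' node value in the same table or `keepOrphans` is set; nodes isolated
#' before filtering are untouched.
#'
#' @param graph a [NetGraph-class].
#' @param table a numeric [AttributeTable-class] (or named numeric vector).
#' @param threshold retain values strictly greater than this.
#' @param keepOrphans keep nodes orphaned by edge removal.
#' @return the filtered [NetGraph-class].
#' @export
filterPositive <- function(graph, table, threshold = 0, keepOrphans = FALSE) {
  stopifnot(is(graph, "NetGraph"))
  entries <- if (is(table, "AttributeTable")) {
    if (table@valueKind != "number") paramError("filtering needs a numeric table")
    table@entries
  } else table
  checkFiniteValues(entries)

  keys <- edgeKeys(graph)
  ids <- graph@nodes$id
  edgeVals <- entries[names(entries) %in% keys]
  nodeVals <- entries[names(entries) %in% ids]
  unknown <- setdiff(names(entries), c(keys, ids))
  if (length(unknown)) {
    message(sprintf("filterPositive: %d table entr%s match no element",
                    length(unknown), if (length(unknown) == 1) "y" else "ies"))
  }

  if (length(edgeVals) || !length(nodeVals)) {
    ## edge filtering (the default reading for an edge-keyed table)
    vals <- setNames(rep(0, length(keys)), keys)
    vals[names(edgeVals)] <- edgeVals
    nMissing <- sum(!keys %in% names(edgeVals))
    if (nMissing) {
      message(sprintf("filterPositive: %d edge(s) missing from table, treated as 0",
                      nMissing))
    }
    keepEdge <- vals > threshold
    e <- graph@edges[keepEdge[keys], , drop = FALSE]
    hadEdge <- ids %in% c(graph@edges$from, graph@edges$to)
    hasEdge <- ids %in% c(e$from, e$to)
    orphaned <- hadEdge & !hasEdge
    posNode <- ids %in% names(nodeVals)[nodeVals > threshold]
    keepNode <- !orphaned | keepOrphans | posNode
    n <- graph@nodes[keepNode, , drop = FALSE]
    e <- e[e$from %in% n$id & e$to %in% n$id, , drop = FALSE]
    netGraph(edges = e, nodes = n, directed = graph@directed)
  } else {
    vals <- setNames(rep(0, length(ids)), ids)
    vals[names(nodeVals)] <- nodeVals
    nMissing <- sum(!ids %in% names(nodeVals))
    if (nMissing) {
      message(sprintf("filterPositive: %d node(s) missing from table, treated as 0",
                      nMissing))
    }
    inducedSubgraph(graph, ids[vals > threshold])
  }
}

#' Split a network by a node attribute
#'
#' One induced subgraph per distinct attribute value (the condition-split
#' used to turn a multi-condition molecular network into per-condition
#' frames). An edge belongs to a subgraph iff both endpoints share that
#' value; cross-group edges are dropped. Nodes missing from the table form
#' an `"unassigned"` group, so the group node sets partition the original
#' node set. Groups are ordered by sorted attribute value, `"unassigned"`
#' last.
#'
#' @param graph a [NetGraph-class].
#' @param table an [AttributeTable-class] (or named vector) over node ids.
#' @return named list of [NetGraph-class] objects, one per group.
#' @export
splitByAttribute <- function(graph, table) {
  stopifnot(is(graph, "NetGraph"))
  entries <- if (is(table, "AttributeTable")) table@entries else table
  ids <- graph@nodes$id
  lab <- setNames(rep(NA_character_, length(ids)), ids)
  known <- intersect(names(entries), ids)
  lab[known] <- as.character(entries[known])
  groups <- idSort(unique(lab[!is.na(lab)]))
  out <- list()
  for (gv in groups) {
    out[[gv]] <- inducedSubgraph(graph, ids[!is.na(lab) & lab == gv])
  }
  if (anyNA(lab)) {
    out[["unassigned"]] <- inducedSubgraph(graph, ids[is.na(lab)])
  }
  out
}

## ---- motion networks ------------------------------------------------------

## structural set-difference events between two graphs: edge deletes, node
## deletes, node inserts, edge inserts, each sorted by id
structuralEvents <- function(old, new) {
  oldKeys <- edgeKeys(old); newKeys <- edgeKeys(new)
  oldIds <- old@nodes$id; newIds <- new@nodes$id
  ev <- list()
  for (k in idSort(setdiff(oldKeys, newKeys))) {
    ev[[length(ev) + 1L]] <- list(kind = "delete", target = "edge", id = k)
  }
  for (id in idSort(setdiff(oldIds, newIds))) {
    ev[[length(ev) + 1L]] <- list(kind = "delete", target = "node", id = id)
  }
  for (id in idSort(setdiff(newIds, oldIds))) {
    i <- match(id, newIds)
    ev[[length(ev) + 1L]] <- list(
      kind = "insert", target = "node", id = id,
      payload = attrsAsList(new@nodes[i, , drop = FALSE], "id"))
  }
  for (k in idSort(setdiff(newKeys, oldKeys))) {
    i <- match(k, newKeys)
    ev[[length(ev) + 1L]] <- list(
      kind = "insert", target = "edge", id = k,
      payload = c(list(from = new@edges$from[i], to = new@edges$to[i],
                       interaction = new@edges$interaction[i]),
                  attrsAsList(new@edges[i, , drop = FALSE],
                              c("from", "to", "interaction"))))
  }
  ev
}

## apply structural events to a graph (styles not involved)
applyStructuralEvents <- function(graph, events) {
  n <- graph@nodes
  e <- graph@edges
  for (ev in events) {
    if (ev$target == "node") {
      if (ev$kind == "delete") {
        if (!ev$id %in% n$id) syncError("delete of unknown node '%s'", ev$id)
        n <- n[n$id != ev$id, , drop = FALSE]
        e <- e[e$from != ev$id & e$to != ev$id, , drop = FALSE]
      } else if (ev$kind == "insert") {
        if (ev$id %in% n$id) syncError("insert of existing node '%s'", ev$id)
        row <- data.frame(id = ev$id, stringsAsFactors = FALSE)
        for (a in names(ev$payload)) row[[a]] <- ev$payload[[a]]
        for (col in setdiff(names(n), names(row))) row[[col]] <- NA
        for (col in setdiff(names(row), names(n))) n[[col]] <- NA
        n <- rbind(n, row[names(n)])
      }
    } else if (ev$target == "edge") {
      if (ev$kind == "delete") {
        keys <- edgeKey(e$from, e$interaction, e$to)
        if (!ev$id %in% keys) syncError("delete of unknown edge '%s'", ev$id)
        e <- e[keys != ev$id, , drop = FALSE]
      } else if (ev$kind == "insert") {
        keys <- edgeKey(e$from, e$interaction, e$to)
        if (ev$id %in% keys) syncError("insert of existing edge '%s'", ev$id)
        p <- ev$payload
        row <- data.frame(from = p$from, to = p$to, interaction = p$interaction,
                          stringsAsFactors = FALSE)
        for (a in setdiff(names(p), c("from", "to", "interaction"))) {
          row[[a]] <- p[[a]]
        }
        for (col in setdiff(names(e), names(row))) row[[col]] <- NA
        for (col in setdiff(names(row), names(e))) e[[col]] <- NA
        e <- rbind(e, row[names(e)])
      }
    }
  }
  netGraph(edges = e, nodes = n, directed = graph@directed)
}

#' Build a motion network from an ordered frame sequence
#'
#' Computes, for each consecutive frame pair, the ordered mutation events
#' (edge deletes, node deletes, node inserts, edge inserts, each sorted by
#' id) that transform frame t-1 into frame t; frame 1 is built from the
#' empty graph. Replaying events 1..t from empty reproduces frame t exactly
#' ([replayMotion()]), and the union graph is the union of all frames.
#'
#' @param frames non-empty list of [NetGraph-class] frames (same
#'   directedness).
#' @param labels unique frame labels, one per frame (default `frame1`, ...).
#' @return a [MotionNetwork-class].
#' @export
buildMotionNetwork <- function(frames, labels = NULL) {
  if (!length(frames)) paramError("at least one frame required")
  if (is.null(labels)) labels <- paste0("frame", seq_along(frames))
  if (length(labels) != length(frames)) {
    configError("need exactly one label per frame")
  }
  if (anyDuplicated(labels)) {
    configError("duplicate frame label '%s'", labels[duplicated(labels)][1L])
  }
  directed <- frames[[1L]]@directed
  empty <- netGraph(directed = directed)
  events <- vector("list", length(frames))
  prev <- empty
  unionNodes <- emptyNodeFrame()
  unionEdges <- emptyEdgeFrame()
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    stopifnot(is(f, "NetGraph"))
    if (f@directed != directed) configError("frames mix directed modes")
    events[[t]] <- structuralEvents(prev, f)
    prev <- f
    unionNodes <- mergeFrames(unionNodes, f@nodes)
    unionEdges <- mergeFrames(unionEdges, f@edges)
  }
  union <- netGraph(edges = unionEdges, nodes = unionNodes, directed = directed)
  new("MotionNetwork", unionGraph = union,
      frameLabels = as.character(labels), events = events)
}

## rbind two frames with differing columns (later rows win on duplicates,
## handled downstream by netGraph's last-wins dedup)
mergeFrames <- function(a, b) {
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  rbind(a, b[names(a)])
}

#' Replay a motion network up to a frame
#'
#' Applies the motion network's mutation events for frames 1..t to the empty
#' graph, reproducing frame t exactly.
#'
#' @param motion a [MotionNetwork-class].
#' @param t frame index (1-based).
#' @return the [NetGraph-class] of frame t.
#' @export
replayMotion <- function(motion, t) {
  stopifnot(is(motion, "MotionNetwork"))
  if (t < 1 || t > length(motion@frameLabels)) {
    paramError("frame index %d out of range", t)
  }
  g <- netGraph(directed = motion@unionGraph@directed)
  for (i in seq_len(t)) g <- applyStructuralEvents(g, motion@events[[i]])
  g
}

#' Animate a motion network on a fixed union layout
#'
#' Produces one [Scene-class] per frame. All frames share the union graph's
#' layout: elements absent from a frame are hidden, not moved, so shared
#' nodes keep identical coordinates across frames and topology changes read
#' as appearance/disappearance. Optionally maps a per-frame column of a
#' time-course table onto node sizes, edge thicknesses or node colours;
#' explicit per-frame styles must only reference elements present in that
#' frame (a violation is an error naming the frame and element).
#'
#' @param motion a [MotionNetwork-class].
#' @param layout a [LayoutState-class] for the union graph; `NULL` computes
#'   one with [multilevelLayout()] and `params`.
#' @param params layout parameters used when `layout` is `NULL`.
#' @param style a [VisualStyle-class].
#' @param timeseries optional [TimeSeriesTable-class] whose frame columns
#'   match the motion's frames (by position).
#' @param map which visual channel the time-course values drive.
#' @param perFrameStyles optional list (one entry per frame) of lists with
#'   any of `nodeSize`, `nodeColor`, `edgeThickness`, `edgeColor`.
#' @return named list of [Scene-class] objects, one per frame.
#' @export
animateMotion <- function(motion, layout = NULL, params = layoutParams(),
                          style = visualStyle(), timeseries = NULL,
                          map = c("size", "thickness", "color"),
                          perFrameStyles = NULL) {
  stopifnot(is(motion, "MotionNetwork"))
  map <- match.arg(map)
  if (is.null(layout)) layout <- multilevelLayout(motion@unionGraph, params)
  labels <- motion@frameLabels
  if (!is.null(timeseries)) {
    stopifnot(is(timeseries, "TimeSeriesTable"))
    if (ncol(timeseries@values) != length(labels)) {
      configError("time-course table has %d frames, motion has %d",
                  ncol(timeseries@values), length(labels))
    }
  }
  scenes <- vector("list", length(labels))
  names(scenes) <- labels
  for (t in seq_along(labels)) {
    g <- replayMotion(motion, t)
    args <- list(graph = g, layout = layout, style = style)
    if (!is.null(timeseries)) {
      v <- timeseries@values[, t]
      names(v) <- rownames(timeseries@values)
      v <- v[names(v) %in% g@nodes$id]        # frame-absent rows are hidden
      if (length(v)) {
        mapped <- switch(map,
          size = list(nodeSize = mapValuesToSize(v, style)),
          thickness = {
            ## node-keyed values drive incident edges' thickness via means
            ek <- edgeKeys(g)
            ev <- (v[g@edges$from] + v[g@edges$to]) / 2
            ev <- setNames(ev[!is.na(ev)], ek[!is.na(ev)])
            list(edgeThickness = if (length(ev)) mapValuesToThickness(ev, style))
          },
          color = list(nodeColor = mapValuesToColor(v, style)))
        args <- c(args, mapped[!vapply(mapped, is.null, logical(1))])
      }
    }
    if (!is.null(perFrameStyles)) {
      st <- perFrameStyles[[t]]
      for (ch in names(st)) {
        present <- if (ch %in% c("nodeSize", "nodeColor")) g@nodes$id else edgeKeys(g)
        bad <- setdiff(names(st[[ch]]), present)
        if (length(bad)) {
          lookupError("frame '%s': style refers to absent element '%s'",
                      labels[t], bad[1L])
        }
        args[[ch]] <- st[[ch]]
      }
    }
    scenes[[t]] <- do.call(makeScene, args)
  }
  scenes
}

#' Export an animation as a scene-JSON sequence
#'
#' @param scenes list of [Scene-class] objects (as from [animateMotion()]).
#' @param file optional path; the sequence is a JSON array of scene objects.
#' @return invisibly, the JSON string.
#' @export
exportAnimation <- function(scenes, file = NULL) {
  parts <- vapply(scenes, exportScene, character(1))
  json <- paste0("[", paste(parts, collapse = ","), "]")
  if (!is.null(file)) writeAtomic(json, file)
  invisible(json)
}
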