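## Visual styles and renderable scenes.

#' Construct a visual style
#'
#' Defaults follow common interactive-network conventions: node radii 10-40
#' units, edge widths 1-8 units, and a blue -> black -> yellow expression
#' heat-map ramp.
#'
#' @param sizeRange,thicknessRange positive `c(min, max)` with min < max.
#' @param colorScheme `"heatmap"` for the built-in ramp, or `"custom"`
#'   together with `ramp`.
#' @param ramp three colour anchors (low, mid, high); ignored unless
#'   `colorScheme = "custom"`.
#' @param defaultColor colour for unmapped elements.
#' @return a [VisualStyle-class].
#' @export
visualStyle <- function(sizeRange = c(10, 40), thicknessRange = c(1, 8),
                        colorScheme = "heatmap", ramp = NULL,
                        defaultColor = "#AAAAAA") {
  resolved <- resolveRamp(colorScheme, ramp)
  new("VisualStyle",
      sizeRange = as.numeric(sizeRange),
      thicknessRange = as.numeric(thicknessRange),
      colorScheme = colorScheme,
      ramp = resolved,
      defaultColor = defaultColor)
}

colorSchemes <- list(
  heatmap = c("#0000FF", "#000000", "#FFFF00")
)

resolveRamp <- function(scheme, ramp = NULL) {
  if (!is.null(ramp)) {
    if (length(ramp) != 3L) configError("a colour ramp needs exactly 3 anchors")
    return(as.character(ramp))
  }
  if (!scheme %in% names(colorSchemes)) {
    configError("unknown colour scheme '%s' (known: %s)", scheme,
                paste(names(colorSchemes), collapse = ", "))
  }
  colorSchemes[[scheme]]
}

#' Build a renderable scene
#'
#' Combines a graph and a layout (which must position exactly the graph's
#' nodes) with per-element visual state. Unspecified sizes/thicknesses start
#' at the midpoint of the style's range; colours start at the style's
#' default. Per-element vectors are stored sorted by id so value-equal
#' scenes serialize identically.
#'
#' @param graph a [NetGraph-class].
#' @param layout a [LayoutState-class] covering exactly the graph's nodes.
#' @param style a [VisualStyle-class] supplying defaults.
#' @param nodeSize,nodeColor optional named vectors (by node id) overriding
#'   the defaults for some or all nodes.
#' @param edgeThickness,edgeColor optional named vectors (by edge key).
#' @param highlighted node ids carrying a highlight label.
#' @param sequence last applied mutation-event sequence number.
#' @return a [Scene-class].
#' @export
makeScene <- function(graph, layout, style = visualStyle(),
                      nodeSize = NULL, nodeColor = NULL,
                      edgeThickness = NULL, edgeColor = NULL,
                      highlighted = character(), sequence = 0) {
  stopifnot(is(graph, "NetGraph"), is(layout, "LayoutState"))
  ids <- graph@nodes$id
  keys <- edgeKeys(graph)

  fill <- function(given, all, default) {
    out <- setNames(rep(default, length(all)), all)
    if (length(given)) {
      unknown <- setdiff(names(given), all)
      if (length(unknown)) {
        lookupError("style refers to unknown element(s): %s",
                    paste(head(unknown, 5), collapse = ", "))
      }
      out[names(given)] <- given
    }
    out[idSort(all)]
  }

  pos <- layout@positions
  if (length(ids) && !all(ids %in% rownames(pos))) {
    lookupError("layout is missing position(s) for node(s): %s",
                paste(head(setdiff(ids, rownames(pos)), 5), collapse = ", "))
  }
  ## canonical (sorted) coverage of exactly the graph's nodes; a layout of a
  ## supergraph (e.g. a union layout) is subset to this frame's nodes
  canon <- if (length(ids)) {
    pos[idSort(ids), , drop = FALSE]
  } else {
    matrix(numeric(), 0, 3, dimnames = list(character(), c("x", "y", "z")))
  }
  colnames(canon) <- c("x", "y", "z")
  layout <- new("LayoutState", positions = canon,
                params = layout@params,
                forceEvaluations = layout@forceEvaluations,
                evalLog = layout@evalLog)

  new("Scene",
      graph = graph,
      layout = layout,
      nodeSize = fill(nodeSize, ids, mean(style@sizeRange)),
      nodeColor = fill(nodeColor, ids, style@defaultColor),
      edgeThickness = fill(edgeThickness, keys, mean(style@thicknessRange)),
      edgeColor = fill(edgeColor, keys, style@defaultColor),
      highlighted = idSort(unique(highlighted)),
      sequence = as.numeric(sequence))
}

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d nodes, %d edges, %d highlighted (sequence %g)\n",
              numNodes(object@graph), numEdges(object@graph),
              length(object@highlighted), object@sequence))
  invisible(object)
})

#' Highlight search hits in a scene
#'
#' Adds a highlight label to the given node ids (for example the result of
#' [findNodes()]). Nothing else about the scene changes.
#'
#' @param scene a [Scene-class].
#' @param ids node ids to highlight (must exist in the scene's graph).
#' @param clear if `TRUE`, previous highlights are dropped first.
#' @return the modified [Scene-class].
#' @export
highlightNodes <- function(scene, ids, clear = FALSE) {
  stopifnot(is(scene, "Scene"))
  bad <- setdiff(ids, scene@graph@nodes$id)
  if (length(bad)) {
    lookupError("cannot highlight unknown node(s): %s",
                paste(head(bad, 5), collapse = ", "))
  }
  base <- if (clear) character() else scene@highlighted
  scene@highlighted <- idSort(unique(c(base, ids)))
  validObject(scene)
  scene
}

#' Compare two scenes for content equality
#'
#' Scenes are equal when graph topology and attributes, positions, styles and
#' highlights all match exactly. The event-sequence counter is ignored by
#' default: it records how a scene was reached, not what it shows.
#'
#' @param a,b [Scene-class] objects.
#' @param ignoreSequence ignore the `@sequence` counters (default `TRUE`).
#' @return logical.
#' @export
sceneIdentical <- function(a, b, ignoreSequence = TRUE) {
  stopifnot(is(a, "Scene"), is(b, "Scene"))
  ## layout bookkeeping (params, eval counts) is provenance, not content
  content <- function(s) {
    list(nodes = s@graph@nodes, edges = s@graph@edges,
         directed = s@graph@directed,
         positions = s@layout@positions,
         nodeSize = s@nodeSize, nodeColor = s@nodeColor,
         edgeThickness = s@edgeThickness, edgeColor = s@edgeColor,
         highlighted = s@highlighted,
         sequence = if (ignoreSequence) 0 else s@sequence)
  }
  identical(content(a), content(b))
}
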