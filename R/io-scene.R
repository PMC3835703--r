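## Scene JSON and GraphML export/import.
##
## Scene JSON is this package's own documented exchange format (schema in
## docs/scene-format.md): a single object with format/version markers, the
## directedness flag, the event-sequence counter, and full per-element
## records (coordinates, size/thickness, colour, highlight flag, attributes).
## Numbers are written at full precision so export -> import is exact.

sceneFormatName <- "netscene3d-scene"
sceneFormatVersion <- 1L

attrsAsList <- function(row, skip) {
  out <- as.list(row[setdiff(names(row), skip)])
  out[!vapply(out, function(v) is.na(v[1L]), logical(1))]
}

#' Export a scene to scene JSON
#'
#' @param scene a [Scene-class] (its layout covers all nodes by
#'   construction; a gap raises an error naming the node).
#' @param file optional path (atomic write).
#' @return invisibly, the JSON string.
#' @export
exportScene <- function(scene, file = NULL) {
  stopifnot(is(scene, "Scene"))
  g <- scene@graph
  pos <- scene@layout@positions
  missingPos <- setdiff(g@nodes$id, rownames(pos))
  if (length(missingPos)) {
    lookupError("unpositioned node(s): %s",
                paste(head(missingPos, 5), collapse = ", "))
  }
  nodes <- lapply(seq_len(nrow(g@nodes)), function(i) {
    id <- g@nodes$id[i]
    c(list(id = id,
           x = pos[id, 1L], y = pos[id, 2L], z = pos[id, 3L],
           size = unname(scene@nodeSize[id]),
           color = unname(scene@nodeColor[id]),
           highlighted = id %in% scene@highlighted),
      list(attributes = attrsAsList(g@nodes[i, , drop = FALSE], "id")))
  })
  keys <- edgeKeys(g)
  edges <- lapply(seq_len(nrow(g@edges)), function(i) {
    k <- keys[i]
    c(list(source = g@edges$from[i],
           target = g@edges$to[i],
           interaction = g@edges$interaction[i],
           thickness = unname(scene@edgeThickness[k]),
           color = unname(scene@edgeColor[k])),
      list(attributes = attrsAsList(g@edges[i, , drop = FALSE],
                                    c("from", "to", "interaction"))))
  })
  payload <- list(format = sceneFormatName, version = sceneFormatVersion,
                  directed = g@directed, sequence = scene@sequence,
                  nodes = nodes, edges = edges)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = FALSE)
  if (!is.null(file)) writeAtomic(as.character(json), file)
  invisible(as.character(json))
}

## rebuild a data.frame from per-element attribute lists (union of names)
bindAttributeLists <- function(base, attrLists) {
  nms <- unique(unlist(lapply(attrLists, names)))
  for (nm in nms) {
    vals <- lapply(attrLists, function(a) if (is.null(a[[nm]])) NA else a[[nm]])
    base[[nm]] <- unlist(vals, use.names = FALSE)
  }
  base
}

#' Import a scene from scene JSON
#'
#' Exact inverse of [exportScene()] on content (layout parameters and
#' force-evaluation counts are provenance and are not serialized).
#'
#' @param file path or connection.
#' @param text alternatively the JSON string.
#' @return a [Scene-class].
#' @export
importScene <- function(file = NULL, text = NULL) {
  json <- paste(sourceLines(file, text), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, sceneFormatName)) {
    formatError("not a %s document", sceneFormatName)
  }
  ids <- vapply(doc$nodes, function(n) n$id, character(1))
  nodes <- bindAttributeLists(data.frame(id = ids, stringsAsFactors = FALSE),
                              lapply(doc$nodes, function(n) n$attributes))
  edges <- NULL
  if (length(doc$edges)) {
    edges <- data.frame(
      from = vapply(doc$edges, function(e) e$source, character(1)),
      to = vapply(doc$edges, function(e) e$target, character(1)),
      interaction = vapply(doc$edges, function(e) e$interaction, character(1)),
      stringsAsFactors = FALSE)
    edges <- bindAttributeLists(edges, lapply(doc$edges, function(e) e$attributes))
  }
  g <- netGraph(edges = edges, nodes = nodes,
                directed = isTRUE(doc$directed))

  pos <- matrix(0, nrow = length(ids), ncol = 3,
                dimnames = list(ids, c("x", "y", "z")))
  size <- setNames(numeric(length(ids)), ids)
  ncol_ <- setNames(character(length(ids)), ids)
  hl <- character()
  for (n in doc$nodes) {
    pos[n$id, ] <- c(n$x, n$y, n$z)
    size[n$id] <- n$size
    ncol_[n$id] <- n$color
    if (isTRUE(n$highlighted)) hl <- c(hl, n$id)
  }
  thick <- numeric(); ecol <- character()
  if (length(doc$edges)) {
    ks <- vapply(doc$edges, function(e) {
      ee <- canonicalEndpoints(
        data.frame(from = e$source, to = e$target,
                   interaction = e$interaction, stringsAsFactors = FALSE),
        g@directed)
      edgeKey(ee$from, ee$interaction, ee$to)
    }, character(1))
    thick <- setNames(vapply(doc$edges, function(e) e$thickness, numeric(1)), ks)
    ecol <- setNames(vapply(doc$edges, function(e) e$color, character(1)), ks)
  }
  layout <- new("LayoutState", positions = pos[idSort(ids), , drop = FALSE],
                params = list(), forceEvaluations = 0,
                evalLog = data.frame())
  makeScene(g, layout,
            nodeSize = size, nodeColor = ncol_,
            edgeThickness = thick, edgeColor = ecol,
            highlighted = hl,
            sequence = if (is.null(doc$sequence)) 0 else doc$sequence)
}

fmtDouble <- function(x) sprintf("%.17g", x)

#' Export a graph + layout to GraphML
#'
#' Coordinates are stored as node attributes `x`, `y`, `z` (double keys);
#' the edge interaction type and any scalar node/edge attributes are stored
#' under their own keys. Coordinates survive a round trip bit-exactly.
#'
#' @param graph a [NetGraph-class].
#' @param layout a [LayoutState-class] covering all nodes (an unpositioned
#'   node is an error naming it).
#' @param file optional path.
#' @return invisibly, the GraphML string.
#' @export
exportGraphML <- function(graph, layout, file = NULL) {
  stopifnot(is(graph, "NetGraph"), is(layout, "LayoutState"))
  pos <- layout@positions
  missingPos <- setdiff(graph@nodes$id, rownames(pos))
  if (length(missingPos)) {
    lookupError("unpositioned node(s): %s",
                paste(head(missingPos, 5), collapse = ", "))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  nattr <- setdiff(names(graph@nodes), "id")
  eattr <- setdiff(names(graph@edges), c("from", "to", "interaction"))
  addKey <- function(id, dom, type) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, "for" = dom, attr.name = id,
                             attr.type = type))
  }
  for (coord in c("x", "y", "z")) addKey(coord, "node", "double")
  for (a in nattr) {
    addKey(a, "node", if (is.numeric(graph@nodes[[a]])) "double" else "string")
  }
  addKey("interaction", "edge", "string")
  for (a in eattr) {
    addKey(a, "edge", if (is.numeric(graph@edges[[a]])) "double" else "string")
  }
  gx <- xml2::xml_add_child(doc, "graph")
  xml2::xml_set_attrs(gx, c(
    id = "G",
    edgedefault = if (graph@directed) "directed" else "undirected"))
  addData <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data")
    xml2::xml_set_attr(d, "key", key)
    xml2::xml_set_text(d, value)
  }
  for (i in seq_len(nrow(graph@nodes))) {
    id <- graph@nodes$id[i]
    nx <- xml2::xml_add_child(gx, "node")
    xml2::xml_set_attr(nx, "id", id)
    for (ci in 1:3) addData(nx, c("x", "y", "z")[ci], fmtDouble(pos[id, ci]))
    for (a in nattr) {
      v <- graph@nodes[[a]][i]
      if (is.na(v)) next
      addData(nx, a, if (is.numeric(v)) fmtDouble(v) else as.character(v))
    }
  }
  for (i in seq_len(nrow(graph@edges))) {
    ex <- xml2::xml_add_child(gx, "edge")
    xml2::xml_set_attrs(ex, c(source = graph@edges$from[i],
                              target = graph@edges$to[i]))
    addData(ex, "interaction", graph@edges$interaction[i])
    for (a in eattr) {
      v <- graph@edges[[a]][i]
      if (is.na(v)) next
      addData(ex, a, if (is.numeric(v)) fmtDouble(v) else as.character(v))
    }
  }
  out <- as.character(doc)
  if (!is.null(file)) writeAtomic(out, file)
  invisible(out)
}

#' Import a GraphML file written by [exportGraphML()]
#'
#' @param file path or connection.
#' @param text alternatively the GraphML string.
#' @return a list with elements `graph` (a [NetGraph-class]) and `layout`
#'   (a [LayoutState-class] holding the recovered coordinates).
#' @export
importGraphML <- function(file = NULL, text = NULL) {
  input <- paste(sourceLines(file, text), collapse = "\n")
  doc <- xml2::read_xml(input)
  xml2::xml_ns_strip(doc)
  keyNodes <- xml2::xml_find_all(doc, "./key")
  keyType <- setNames(xml2::xml_attr(keyNodes, "attr.type"),
                      xml2::xml_attr(keyNodes, "id"))
  gx <- xml2::xml_find_first(doc, "./graph")
  directed <- identical(xml2::xml_attr(gx, "edgedefault"), "directed")

  readData <- function(el) {
    ds <- xml2::xml_find_all(el, "./data")
    setNames(xml2::xml_text(ds), xml2::xml_attr(ds, "key"))
  }
  nodeEls <- xml2::xml_find_all(gx, "./node")
  ids <- xml2::xml_attr(nodeEls, "id")
  nodeData <- lapply(nodeEls, readData)
  pos <- matrix(0, nrow = length(ids), ncol = 3,
                dimnames = list(ids, c("x", "y", "z")))
  attrLists <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- nodeData[[i]]
    pos[i, ] <- as.numeric(d[c("x", "y", "z")])
    rest <- d[setdiff(names(d), c("x", "y", "z"))]
    attrLists[[i]] <- lapply(setNames(as.list(rest), names(rest)), function(v) v)
    for (nm in names(attrLists[[i]])) {
      if (identical(keyType[[nm]], "double")) {
        attrLists[[i]][[nm]] <- as.numeric(attrLists[[i]][[nm]])
      }
    }
  }
  nodes <- bindAttributeLists(data.frame(id = ids, stringsAsFactors = FALSE),
                              attrLists)
  edgeEls <- xml2::xml_find_all(gx, "./edge")
  edges <- NULL
  if (length(edgeEls)) {
    eData <- lapply(edgeEls, readData)
    edges <- data.frame(
      from = xml2::xml_attr(edgeEls, "source"),
      to = xml2::xml_attr(edgeEls, "target"),
      interaction = vapply(eData, function(d) {
        if ("interaction" %in% names(d)) d[["interaction"]] else "pp"
      }, character(1)),
      stringsAsFactors = FALSE)
    eAttrs <- lapply(eData, function(d) {
      rest <- as.list(d[setdiff(names(d), "interaction")])
      for (nm in names(rest)) {
        if (identical(keyType[[nm]], "double")) rest[[nm]] <- as.numeric(rest[[nm]])
      }
      rest
    })
    edges <- bindAttributeLists(edges, eAttrs)
  }
  graph <- netGraph(edges = edges, nodes = nodes, directed = directed)
  layout <- new("LayoutState",
                positions = pos[idSort(ids), , drop = FALSE],
                params = list(), forceEvaluations = 0, evalLog = data.frame())
  list(graph = graph, layout = layout)
}
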