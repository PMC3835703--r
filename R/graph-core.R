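## Attributed graph data model: construction, accessors, search.

#' Edge keys
#'
#' The canonical textual identity of an edge, `"from|interaction|to"`, after
#' undirected canonicalization (endpoints swapped so `from <= to` in C
#' collation). Used wherever edges are addressed by id: attribute lookup,
#' per-edge styles, mutation events.
#'
#' @param from,interaction,to character vectors (recycled).
#' @return character vector of keys.
#' @export
edgeKey <- function(from, interaction, to) {
  paste(from, interaction, to, sep = "|")
}

#' @param graph a [NetGraph-class].
#' @rdname edgeKey
#' @export
edgeKeys <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(character())
  edgeKey(e$from, e$interaction, e$to)
}

## Swap endpoints of undirected edges into canonical (C-collation) order.
canonicalEndpoints <- function(edges, directed) {
  if (!directed && nrow(edges)) {
    swap <- rankOf(edges$from, edges$to) > rankOf(edges$to, edges$from)
    if (any(swap)) {
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
  }
  edges
}

## C-collation pairwise comparison helper: rank of a within sort of c(a,b).
rankOf <- function(a, b) {
  ## TRUE where a sorts after b under radix (C locale) ordering
  n <- length(a)
  o <- idOrder(c(a, b))
  r <- integer(2L * n)
  r[o] <- seq_along(o)
  r[seq_len(n)]
}

emptyNodeFrame <- function() data.frame(id = character(), stringsAsFactors = FALSE)
emptyEdgeFrame <- function() data.frame(
  from = character(), to = character(), interaction = character(),
  stringsAsFactors = FALSE
)

#' Construct an attributed network
#'
#' Builds a [NetGraph-class] from an edge table and/or a node table. Missing
#' endpoint nodes are created automatically (mirroring SIF semantics, so an
#' edge list alone always yields a well-formed graph). Duplicate edges (same
#' source, interaction, target after undirected canonicalization) collapse to
#' one, keeping the last-seen attributes; duplicate node rows likewise keep
#' the last. Nodes and edges are stored sorted by id so value-equal graphs
#' are `identical()`.
#'
#' @param edges `NULL`, or a data.frame with character columns `from` and
#'   `to`, optionally `interaction` (default `"pp"`) and attribute columns.
#' @param nodes `NULL`, a character vector of node ids, or a data.frame with
#'   an `id` column plus attribute columns.
#' @param directed logical; undirected is the default mode (assembly-derived
#'   orientation-kept graphs are directed).
#' @return a [NetGraph-class].
#' @examples
#' g <- netGraph(data.frame(from = "A", to = "B", interaction = "pp"))
#' numNodes(g); numEdges(g)
#' @export
netGraph <- function(edges = NULL, nodes = NULL, directed = FALSE) {
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    e <- emptyEdgeFrame()
  } else {
    e <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(e))) {
      paramError("edge table needs 'from' and 'to' columns")
    }
    if (!"interaction" %in% names(e)) e$interaction <- "pp"
    e$from <- as.character(e$from)
    e$to <- as.character(e$to)
    e$interaction <- as.character(e$interaction)
    e <- e[c("from", "to", "interaction",
             setdiff(names(e), c("from", "to", "interaction")))]
    e <- canonicalEndpoints(e, directed)
    key <- edgeKey(e$from, e$interaction, e$to)
    e <- e[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    e <- e[idOrder(e$from, e$interaction, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }

  if (is.null(nodes)) {
    n <- emptyNodeFrame()
  } else if (is.character(nodes)) {
    n <- data.frame(id = nodes, stringsAsFactors = FALSE)
  } else {
    n <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!"id" %in% names(n)) paramError("node table needs an 'id' column")
    n$id <- as.character(n$id)
    n <- n[c("id", setdiff(names(n), "id"))]
  }
  n <- n[!duplicated(n$id, fromLast = TRUE), , drop = FALSE]
  missing <- setdiff(c(e$from, e$to), n$id)
  if (length(missing)) {
    extra <- emptyNodeFrame()
    extra[seq_along(missing), "id"] <- missing
    for (col in setdiff(names(n), "id")) extra[[col]] <- NA
    n <- rbind(n, extra[names(n)])
  }
  n <- n[idOrder(n$id), , drop = FALSE]
  rownames(n) <- NULL

  new("NetGraph", nodes = n, edges = e, directed = isTRUE(directed))
}

#' @rdname graphAccessors
#' @export
setGeneric("numNodes", function(graph) standardGeneric("numNodes"))
#' @rdname graphAccessors
#' @export
setGeneric("numEdges", function(graph) standardGeneric("numEdges"))
#' @rdname graphAccessors
#' @export
setGeneric("nodeIds", function(graph) standardGeneric("nodeIds"))
#' @rdname graphAccessors
#' @export
setGeneric("graphNodes", function(graph) standardGeneric("graphNodes"))
#' @rdname graphAccessors
#' @export
setGeneric("graphEdges", function(graph) standardGeneric("graphEdges"))
#' @rdname graphAccessors
#' @export
setGeneric("isDirected", function(graph) standardGeneric("isDirected"))

#' Graph accessors
#'
#' Read-only access to a [NetGraph-class]'s content: node/edge counts, node
#' ids, the node and edge tables (attribute columns included) and the
#' directedness flag.
#'
#' @param graph a [NetGraph-class].
#' @return counts, a character vector of ids, data.frames, or a logical.
#' @name graphAccessors
#' @aliases numNodes numEdges nodeIds graphNodes graphEdges isDirected
NULL

#' @rdname graphAccessors
setMethod("numNodes", "NetGraph", function(graph) nrow(graph@nodes))
#' @rdname graphAccessors
setMethod("numEdges", "NetGraph", function(graph) nrow(graph@edges))
#' @rdname graphAccessors
setMethod("nodeIds", "NetGraph", function(graph) graph@nodes$id)
#' @rdname graphAccessors
setMethod("graphNodes", "NetGraph", function(graph) graph@nodes)
#' @rdname graphAccessors
setMethod("graphEdges", "NetGraph", function(graph) graph@edges)
#' @rdname graphAccessors
setMethod("isDirected", "NetGraph", function(graph) graph@directed)

setMethod("show", "NetGraph", function(object) {
  cat(sprintf("NetGraph: %d nodes, %d edges (%s)\n",
              nrow(object@nodes), nrow(object@edges),
              if (object@directed) "directed" else "undirected"))
  nattr <- setdiff(names(object@nodes), "id")
  eattr <- setdiff(names(object@edges), c("from", "to", "interaction"))
  if (length(nattr)) cat("  node attributes:", paste(nattr, collapse = ", "), "\n")
  if (length(eattr)) cat("  edge attributes:", paste(eattr, collapse = ", "), "\n")
  invisible(object)
})

#' Search nodes by identifier substring
#'
#' Returns the ids of all nodes whose identifier contains `query` as a
#' case-insensitive substring, sorted lexicographically. This mirrors an
#' interactive search box: ids stay case-sensitive for identity, matching is
#' case-insensitive, and no match is not an error (empty result). The result
#' depends only on the graph's node set, never on any layout.
#'
#' @param graph a [NetGraph-class].
#' @param query non-empty search string (matched literally, not as a regex).
#' @return character vector of matching node ids (possibly empty), sorted.
#' @examples
#' g <- netGraph(nodes = c("contig510", "contig511"))
#' findNodes(g, "510")
#' @export
findNodes <- function(graph, query) {
  stopifnot(is(graph, "NetGraph"))
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    paramError("search query must be a non-empty string")
  }
  ids <- graph@nodes$id
  idSort(ids[grepl(tolower(query), tolower(ids), fixed = TRUE)])
}

#' Look up the attributes of a node or an edge
#'
#' Returns the full attribute mapping of one element as a named list,
#' dropping unset (`NA`) attributes. The element is addressed either by node
#' id or by edge key (`"from|interaction|to"`, see [edgeKey()]).
#'
#' @param graph a [NetGraph-class].
#' @param elementId a node id or an edge key.
#' @return named list of attribute values (empty for an element without
#'   attributes).
#' @export
getAttributes <- function(graph, elementId) {
  stopifnot(is(graph, "NetGraph"), is.character(elementId), length(elementId) == 1L)
  n <- graph@nodes
  i <- match(elementId, n$id)
  if (!is.na(i)) {
    row <- as.list(n[i, setdiff(names(n), "id"), drop = FALSE])
  } else {
    keys <- edgeKeys(graph)
    j <- match(elementId, keys)
    if (is.na(j)) {
      lookupError("no node or edge with identifier '%s'", elementId)
    }
    e <- graph@edges
    row <- as.list(e[j, setdiff(names(e), c("from", "to", "interaction")),
                     drop = FALSE])
  }
  row[!vapply(row, function(v) is.na(v[1L]), logical(1))]
}

#' Induced subgraph
#'
#' The subgraph on a node subset: the chosen nodes and every edge whose two
#' endpoints are both kept. Attributes travel along.
#'
#' @param graph a [NetGraph-class].
#' @param ids node ids to keep (unknown ids are an error).
#' @return a [NetGraph-class].
#' @export
inducedSubgraph <- function(graph, ids) {
  stopifnot(is(graph, "NetGraph"))
  bad <- setdiff(ids, graph@nodes$id)
  if (length(bad)) {
    lookupError("unknown node id(s): %s", paste(head(bad, 5), collapse = ", "))
  }
  n <- graph@nodes[graph@nodes$id %in% ids, , drop = FALSE]
  e <- graph@edges[graph@edges$from %in% ids & graph@edges$to %in% ids, ,
                   drop = FALSE]
  netGraph(edges = e, nodes = n, directed = graph@directed)
}

## Adjacency list (neighbour ids per node), self-loops excluded, neighbours
## sorted; directedness is ignored (used by layout and bubble search).
adjacencyList <- function(graph) {
  ids <- graph@nodes$id
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character()
  e <- graph@edges
  if (nrow(e)) {
    keep <- e$from != e$to
    for (i in which(keep)) {
      adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
      adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
    }
    adj <- lapply(adj, function(v) idSort(unique(v)))
  }
  adj
}
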