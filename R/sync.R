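## Scene synchronization: diff/apply mutation events, in-process
## server/client sessions, and NDJSON event streams over R connections.
## Wire schema documented in docs/protocol.md.

nodeInsertPayload <- function(scene, id) {
  g <- scene@graph
  i <- match(id, g@nodes$id)
  pos <- scene@layout@positions
  list(id = id,
       x = pos[id, 1L], y = pos[id, 2L], z = pos[id, 3L],
       size = unname(scene@nodeSize[id]),
       color = unname(scene@nodeColor[id]),
       highlighted = id %in% scene@highlighted,
       attributes = attrsAsList(g@nodes[i, , drop = FALSE], "id"))
}

edgeInsertPayload <- function(scene, key) {
  g <- scene@graph
  i <- match(key, edgeKeys(g))
  list(from = g@edges$from[i], to = g@edges$to[i],
       interaction = g@edges$interaction[i],
       thickness = unname(scene@edgeThickness[key]),
       color = unname(scene@edgeColor[key]),
       attributes = attrsAsList(g@edges[i, , drop = FALSE],
                                c("from", "to", "interaction")))
}

nodeStyleRecord <- function(scene, id) {
  pos <- scene@layout@positions
  list(x = pos[id, 1L], y = pos[id, 2L], z = pos[id, 3L],
       size = unname(scene@nodeSize[id]),
       color = unname(scene@nodeColor[id]),
       highlighted = id %in% scene@highlighted)
}

edgeStyleRecord <- function(scene, key) {
  list(thickness = unname(scene@edgeThickness[key]),
       color = unname(scene@edgeColor[key]))
}

#' Diff two scenes into an ordered mutation-event list
#'
#' Computes the minimal ordered event set transforming `old` into `new`:
#' structural deletes (edges, then nodes), structural inserts (nodes, then
#' edges), then style/position updates for surviving elements — each class
#' sorted by element id. `sceneDiff(x, x)` is empty, and
#' `applyEvents(x, sceneDiff(x, y))` reproduces `y` exactly. Sequence
#' numbers continue from `old@sequence`.
#'
#' @param old,new [Scene-class] objects with the same directedness.
#' @return list of mutation events; each event is a list with fields
#'   `seq` (monotone integer), `kind` (`insert` / `delete` / `update`),
#'   `target` (`node` / `edge` / `style`), `id` and (for inserts/updates)
#'   `payload`.
#' @export
sceneDiff <- function(old, new) {
  stopifnot(is(old, "Scene"), is(new, "Scene"))
  if (old@graph@directed != new@graph@directed) {
    syncError("cannot diff scenes with different directedness")
  }
  ev <- structuralEvents(old@graph, new@graph)
  ## enrich structural inserts with the new scene's visual state
  for (i in seq_along(ev)) {
    if (ev[[i]]$kind == "insert") {
      ev[[i]]$payload <- if (ev[[i]]$target == "node") {
        nodeInsertPayload(new, ev[[i]]$id)
      } else {
        edgeInsertPayload(new, ev[[i]]$id)
      }
    }
  }
  ## attribute updates on surviving elements ride as update/node|edge events
  commonIds <- idSort(intersect(old@graph@nodes$id, new@graph@nodes$id))
  for (id in commonIds) {
    ao <- getAttributes(old@graph, id); an <- getAttributes(new@graph, id)
    if (!identical(ao, an)) {
      ev[[length(ev) + 1L]] <- list(kind = "update", target = "node", id = id,
                                    payload = list(attributes = an))
    }
  }
  commonKeys <- idSort(intersect(edgeKeys(old@graph), edgeKeys(new@graph)))
  for (k in commonKeys) {
    ao <- getAttributes(old@graph, k); an <- getAttributes(new@graph, k)
    if (!identical(ao, an)) {
      ev[[length(ev) + 1L]] <- list(kind = "update", target = "edge", id = k,
                                    payload = list(attributes = an))
    }
  }
  ## style/position updates, nodes then edges, sorted by id
  for (id in commonIds) {
    so <- nodeStyleRecord(old, id); sn <- nodeStyleRecord(new, id)
    if (!identical(so, sn)) {
      ev[[length(ev) + 1L]] <- list(kind = "update", target = "style", id = id,
                                    payload = c(list(element = "node"), sn))
    }
  }
  for (k in commonKeys) {
    so <- edgeStyleRecord(old, k); sn <- edgeStyleRecord(new, k)
    if (!identical(so, sn)) {
      ev[[length(ev) + 1L]] <- list(kind = "update", target = "style", id = k,
                                    payload = c(list(element = "edge"), sn))
    }
  }
  for (i in seq_along(ev)) ev[[i]]$seq <- old@sequence + i
  lapply(ev, function(e) e[c("seq", "kind", "target", "id",
                             intersect("payload", names(e)))])
}

#' Apply mutation events to a scene
#'
#' Replays an ordered event list. Sequence numbers must continue the
#' scene's own counter contiguously: a stale event (sequence at or below
#' the scene's counter) or an out-of-order event is rejected with a
#' synchronization error carrying the sequence number, as is an insert of
#' an existing id or a delete/update of a missing one.
#' `applyEvents(x, list())` is `x`.
#'
#' @param scene a [Scene-class].
#' @param events event list as produced by [sceneDiff()].
#' @param style a [VisualStyle-class] supplying defaults for inserted
#'   elements that carry no explicit style.
#' @return the updated [Scene-class] (sequence counter advanced).
#' @export
applyEvents <- function(scene, events, style = visualStyle()) {
  stopifnot(is(scene, "Scene"))
  seqNo <- scene@sequence
  g <- scene@graph
  pos <- scene@layout@positions
  nodeSize <- scene@nodeSize; nodeColor <- scene@nodeColor
  edgeThickness <- scene@edgeThickness; edgeColor <- scene@edgeColor
  highlighted <- scene@highlighted

  for (ev in events) {
    if (is.null(ev$seq) || ev$seq <= seqNo) {
      syncError("stale event (sequence %s, scene at %g)",
                as.character(ev$seq), seqNo)
    }
    if (ev$seq != seqNo + 1) {
      syncError("out-of-order event: expected sequence %g, got %g",
                seqNo + 1, ev$seq)
    }
    seqNo <- ev$seq
    tgt <- ev$target; kind <- ev$kind; id <- ev$id
    if (tgt == "node" && kind == "insert") {
      p <- ev$payload
      g <- applyStructuralEvents(g, list(list(kind = "insert", target = "node",
                                              id = id,
                                              payload = p$attributes)))
      pos <- rbind(pos, matrix(c(p$x, p$y, p$z), nrow = 1,
                               dimnames = list(id, colnames(pos))))
      nodeSize[id] <- if (is.null(p$size)) mean(style@sizeRange) else p$size
      nodeColor[id] <- if (is.null(p$color)) style@defaultColor else p$color
      if (isTRUE(p$highlighted)) highlighted <- c(highlighted, id)
    } else if (tgt == "node" && kind == "delete") {
      g <- applyStructuralEvents(g, list(list(kind = "delete", target = "node",
                                              id = id)))
      pos <- pos[rownames(pos) != id, , drop = FALSE]
      nodeSize <- nodeSize[names(nodeSize) != id]
      nodeColor <- nodeColor[names(nodeColor) != id]
      highlighted <- setdiff(highlighted, id)
      keep <- names(edgeThickness) %in% edgeKeys(g)
      edgeThickness <- edgeThickness[keep]
      edgeColor <- edgeColor[names(edgeColor) %in% edgeKeys(g)]
    } else if (tgt == "edge" && kind == "insert") {
      p <- ev$payload
      g <- applyStructuralEvents(g, list(list(
        kind = "insert", target = "edge", id = id,
        payload = c(list(from = p$from, to = p$to, interaction = p$interaction),
                    p$attributes))))
      edgeThickness[id] <- if (is.null(p$thickness)) mean(style@thicknessRange) else p$thickness
      edgeColor[id] <- if (is.null(p$color)) style@defaultColor else p$color
    } else if (tgt == "edge" && kind == "delete") {
      g <- applyStructuralEvents(g, list(list(kind = "delete", target = "edge",
                                              id = id)))
      edgeThickness <- edgeThickness[names(edgeThickness) != id]
      edgeColor <- edgeColor[names(edgeColor) != id]
    } else if (kind == "update" && tgt %in% c("node", "edge")) {
      present <- if (tgt == "node") id %in% g@nodes$id else id %in% edgeKeys(g)
      if (!present) syncError("sequence %g: update of unknown %s '%s'",
                              ev$seq, tgt, id)
      att <- ev$payload$attributes
      if (tgt == "node") {
        i <- match(id, g@nodes$id)
        n <- g@nodes
        for (col in setdiff(names(n), "id")) n[i, col] <- NA
        for (a in names(att)) n[i, a] <- att[[a]]
        g <- netGraph(edges = g@edges, nodes = n, directed = g@directed)
      } else {
        i <- match(id, edgeKeys(g))
        e <- g@edges
        for (col in setdiff(names(e), c("from", "to", "interaction"))) e[i, col] <- NA
        for (a in names(att)) e[i, a] <- att[[a]]
        g <- netGraph(edges = e, nodes = g@nodes, directed = g@directed)
      }
    } else if (kind == "update" && tgt == "style") {
      p <- ev$payload
      if (identical(p$element, "node")) {
        if (!id %in% g@nodes$id) {
          syncError("sequence %g: style update for unknown node '%s'", ev$seq, id)
        }
        pos[id, ] <- c(p$x, p$y, p$z)
        nodeSize[id] <- p$size
        nodeColor[id] <- p$color
        highlighted <- if (isTRUE(p$highlighted)) {
          union(highlighted, id)
        } else setdiff(highlighted, id)
      } else {
        if (!id %in% edgeKeys(g)) {
          syncError("sequence %g: style update for unknown edge '%s'", ev$seq, id)
        }
        edgeThickness[id] <- p$thickness
        edgeColor[id] <- p$color
      }
    } else {
      syncError("sequence %g: unknown event kind/target '%s/%s'",
                ev$seq, kind, tgt)
    }
  }

  layout <- new("LayoutState",
                positions = pos[idSort(rownames(pos)), , drop = FALSE],
                params = scene@layout@params,
                forceEvaluations = scene@layout@forceEvaluations,
                evalLog = scene@layout@evalLog)
  makeScene(g, layout, style = style,
            nodeSize = nodeSize, nodeColor = nodeColor,
            edgeThickness = edgeThickness, edgeColor = edgeColor,
            highlighted = highlighted, sequence = seqNo)
}

## ---- in-process session (server + read-only mirror clients) ---------------

#' Scene synchronization sessions
#'
#' `syncServer()` starts an in-process session holding the authoritative
#' scene. `publishScene()` diffs a new scene against the session state and
#' appends the resulting events to the session log (server-assigned,
#' strictly increasing sequence numbers). `connectClient()` joins a client:
#' it receives a full-state snapshot and, on each [clientSync()], the
#' events logged since it last looked — so every client that has consumed
#' the same stream prefix holds an identical scene, and a client may join
#' (or rejoin after disconnecting) at any time and converge from a fresh
#' snapshot.
#'
#' @param scene the initial authoritative [Scene-class].
#' @return `syncServer()`: a session object; `connectClient()`: a client
#'   object; `clientSync()`: the client's updated [Scene-class];
#'   `clientScene()`: the client's current scene without syncing.
#' @name syncSession
NULL

#' @rdname syncSession
#' @export
syncServer <- function(scene) {
  stopifnot(is(scene, "Scene"))
  env <- new.env(parent = emptyenv())
  env$scene <- scene
  env$initialScene <- scene
  env$events <- list()
  structure(env, class = "syncServer")
}

#' @rdname syncSession
#' @param server a session from [syncServer()].
#' @param newScene the scene replacing the session state.
#' @export
publishScene <- function(server, newScene) {
  stopifnot(inherits(server, "syncServer"))
  ev <- sceneDiff(server$scene, newScene)
  server$events <- c(server$events, ev)
  server$scene <- applyEvents(server$scene, ev)
  invisible(length(ev))
}

#' @rdname syncSession
#' @export
connectClient <- function(server) {
  stopifnot(inherits(server, "syncServer"))
  env <- new.env(parent = emptyenv())
  env$server <- server
  env$scene <- server$scene          # snapshot join
  env$cursor <- length(server$events)
  structure(env, class = "syncClient")
}

#' @rdname syncSession
#' @param client a client from [connectClient()].
#' @export
clientSync <- function(client) {
  stopifnot(inherits(client, "syncClient"))
  evs <- client$server$events
  if (client$cursor < length(evs)) {
    pending <- evs[(client$cursor + 1L):length(evs)]
    client$scene <- applyEvents(client$scene, pending)
    client$cursor <- length(evs)
  }
  client$scene
}

#' @rdname syncSession
#' @export
clientScene <- function(client) client$scene

## ---- NDJSON event streams -------------------------------------------------

eventToJSON <- function(ev) {
  as.character(jsonlite::toJSON(c(list(type = "event"), ev),
                                auto_unbox = TRUE, digits = I(17), null = "null"))
}

#' Serialize / replay a scene stream
#'
#' The wire format of a session is newline-delimited JSON: a `snapshot`
#' record (the full scene, scene-JSON payload) followed by one `event`
#' record per mutation event. `writeSceneStream()` emits the session's
#' snapshot-then-deltas stream from a given event index (what a client
#' joining at that point would receive); `readSceneStream()` consumes such
#' a stream and returns the reconstructed scene. Two consumers of the same
#' stream hold byte-identical scenes on re-serialization.
#'
#' @param server a [syncServer()] session.
#' @param file path or writable connection.
#' @param from event index after which to stream (0 = full history; the
#'   snapshot is then the initial scene rewound to that point).
#' @return `writeSceneStream()`: invisibly, the lines written;
#'   `readSceneStream()`: a [Scene-class].
#' @export
writeSceneStream <- function(server, file = NULL, from = 0) {
  stopifnot(inherits(server, "syncServer"))
  evs <- server$events
  if (from < 0 || from > length(evs)) paramError("invalid stream start %g", from)
  ## rewind: replay only events up to `from` onto a cheap base if needed
  base <- server$scene
  if (from < length(evs)) {
    ## reconstruct the scene as of event `from` by replaying from scratch
    base <- replayStream(serverInitialScene(server), evs, upTo = from)
  }
  lines <- c(
    as.character(jsonlite::toJSON(
      list(type = "snapshot", scene = jsonlite::fromJSON(exportScene(base),
                                                         simplifyVector = FALSE)),
      auto_unbox = TRUE, digits = I(17), null = "null")),
    vapply(evs[seq_len(length(evs) - from) + from], eventToJSON, character(1))
  )
  if (!is.null(file)) {
    if (inherits(file, "connection")) writeLines(lines, file)
    else writeAtomic(lines, file)
  }
  invisible(lines)
}

## the session's scene before any event (replay support)
serverInitialScene <- function(server) server$initialScene

replayStream <- function(scene, events, upTo) {
  if (upTo > 0) scene <- applyEvents(scene, events[seq_len(upTo)])
  scene
}

#' @rdname writeSceneStream
#' @param text alternatively the stream content as lines.
#' @export
readSceneStream <- function(file = NULL, text = NULL) {
  lines <- sourceLines(file, text)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) formatError("scene stream: empty input")
  first <- jsonlite::fromJSON(lines[1L], simplifyVector = FALSE)
  if (!identical(first$type, "snapshot")) {
    formatError("scene stream line 1: expected a snapshot record")
  }
  scene <- importScene(text = as.character(
    jsonlite::toJSON(first$scene, auto_unbox = TRUE, digits = I(17), null = "null")))
  events <- lapply(lines[-1L], function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    if (!identical(rec$type, "event")) {
      formatError("scene stream: non-event record after snapshot")
    }
    rec$type <- NULL
    rec
  })
  if (length(events)) scene <- applyEvents(scene, events)
  scene
}
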