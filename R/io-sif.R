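## SIF (Simple Interaction Format) reader/writer.

#' Read a SIF network
#'
#' Parses Cytoscape's Simple Interaction Format. Each line is either
#' `source interaction target [target2 ...]` (one edge per listed target) or
#' a single token (an isolated node). Blank lines are skipped. Cytoscape's
#' dual dialect is honoured: if a line contains a tab it is split on tabs,
#' otherwise on runs of whitespace — so node names with internal spaces
#' survive in tab-delimited files.
#'
#' A line with exactly two tokens is malformed (an interaction type without a
#' target) and raises a format error carrying the line number.
#'
#' @param file path or connection to read from.
#' @param text alternatively, the SIF content as a character vector of lines
#'   (or one string with embedded newlines).
#' @param directed build a directed graph (default undirected, the SIF
#'   convention for interaction networks).
#' @return a [NetGraph-class].
#' @examples
#' g <- readSIF(text = c("A pp B C", "X"))
#' numNodes(g); numEdges(g)
#' @export
readSIF <- function(file = NULL, text = NULL, directed = FALSE) {
  lines <- sourceLines(file, text)
  from <- character(); to <- character(); itype <- character()
  isolated <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (grepl("\t", line, fixed = TRUE)) {
      toks <- trimws(strsplit(line, "\t", fixed = TRUE)[[1L]])
      toks <- toks[nzchar(toks)]
    } else {
      toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    }
    if (length(toks) == 1L) {
      isolated <- c(isolated, toks)
    } else if (length(toks) == 2L) {
      formatError("SIF line %d: interaction type without target (2 tokens)", i)
    } else {
      targets <- toks[-(1:2)]
      from <- c(from, rep(toks[1L], length(targets)))
      itype <- c(itype, rep(toks[2L], length(targets)))
      to <- c(to, targets)
    }
  }
  edges <- if (length(from)) {
    data.frame(from = from, to = to, interaction = itype,
               stringsAsFactors = FALSE)
  } else NULL
  netGraph(edges = edges, nodes = isolated, directed = directed)
}

#' Write a SIF network
#'
#' One line per edge (`from interaction to`); isolated nodes are emitted as
#' single-token lines. Attributes are not representable in SIF and are
#' dropped; `readSIF(writeSIF(g))` recovers the topology exactly.
#'
#' @param graph a [NetGraph-class].
#' @param file optional path; when given, lines are written atomically.
#' @param sep token separator (default tab, Cytoscape's preferred dialect).
#' @return invisibly, the character vector of lines.
#' @export
writeSIF <- function(graph, file = NULL, sep = "\t") {
  stopifnot(is(graph, "NetGraph"))
  e <- graph@edges
  lines <- character()
  if (nrow(e)) lines <- paste(e$from, e$interaction, e$to, sep = sep)
  touched <- unique(c(e$from, e$to))
  lines <- c(lines, setdiff(graph@nodes$id, touched))
  if (!is.null(file)) writeAtomic(lines, file)
  invisible(lines)
}
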