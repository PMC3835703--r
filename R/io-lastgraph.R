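## Velvet LastGraph reader/writer.

#' Read a Velvet LastGraph assembly graph
#'
#' Parses the final graph dump of the Velvet assembler. Interpreted records:
#'
#' * header: `node_count sequence_count hash_length ...` (extra columns
#'   ignored);
#' * `NODE <id> <length> <cov...>` followed by exactly two sequence lines
#'   (stored verbatim, not validated as DNA); the column layout after
#'   `length` varies across Velvet versions, so remaining numeric columns
#'   are kept as coverage values `cov1`, `cov2`, ... without interpretation;
#' * `ARC <start> <end> <multiplicity>` with orientation-signed node ids.
#'
#' Short-read tracking records (`NR`, `SEQ` blocks) are skipped. The
#' declared `node_count` must match the number of `NODE` blocks, and every
#' arc must reference declared node ids; violations are format errors.
#'
#' @param file path or connection.
#' @param text alternatively the content as lines.
#' @return an [AssemblyGraph-class].
#' @export
readLastGraph <- function(file = NULL, text = NULL) {
  lines <- sourceLines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) formatError("LastGraph: empty input")
  header <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  hnum <- suppressWarnings(as.numeric(header))
  if (length(header) < 3L || anyNA(hnum[1:3])) {
    formatError("LastGraph line 1: header must be 'node_count sequence_count hash_length ...'")
  }
  nodeCount <- hnum[1L]; seqCount <- hnum[2L]; hashLength <- hnum[3L]

  ids <- integer(); lens <- numeric(); covs <- list()
  seqs <- list()
  arcFrom <- integer(); arcTo <- integer(); arcMult <- numeric()
  arcLine <- integer()

  i <- 2L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    rec <- toks[1L]
    if (identical(rec, "NODE")) {
      if (length(toks) < 3L) formatError("LastGraph line %d: short NODE record", i)
      vals <- suppressWarnings(as.numeric(toks[-1L]))
      if (anyNA(vals[1:2])) {
        formatError("LastGraph line %d: NODE id/length not numeric", i)
      }
      if (i + 2L > n) formatError("LastGraph line %d: NODE block truncated", i)
      ids <- c(ids, as.integer(vals[1L]))
      lens <- c(lens, vals[2L])
      covs[[length(covs) + 1L]] <- vals[-(1:2)]
      seqs[[as.character(as.integer(vals[1L]))]] <- lines[i + (1:2)]
      i <- i + 3L
      next
    }
    if (identical(rec, "ARC")) {
      vals <- suppressWarnings(as.numeric(toks[-1L]))
      if (length(vals) != 3L || anyNA(vals)) {
        formatError("LastGraph line %d: ARC needs 'start end multiplicity'", i)
      }
      arcFrom <- c(arcFrom, as.integer(vals[1L]))
      arcTo <- c(arcTo, as.integer(vals[2L]))
      arcMult <- c(arcMult, vals[3L])
      arcLine <- c(arcLine, i)
      i <- i + 1L
      next
    }
    ## NR / SEQ short-read tracking blocks and anything else: skipped verbatim
    i <- i + 1L
  }

  if (length(ids) != nodeCount) {
    formatError("LastGraph: header declares %d nodes but %d NODE blocks found",
                nodeCount, length(ids))
  }
  undeclared <- !(abs(arcFrom) %in% ids & abs(arcTo) %in% ids)
  if (any(undeclared)) {
    j <- which(undeclared)[1L]
    formatError("LastGraph line %d: ARC references undeclared node id", arcLine[j])
  }

  ncov <- if (length(covs)) max(lengths(covs)) else 0L
  nodes <- data.frame(id = ids, length = lens)
  for (c_ in seq_len(ncov)) {
    nodes[[paste0("cov", c_)]] <- vapply(covs, function(v) {
      if (length(v) >= c_) v[c_] else NA_real_
    }, numeric(1))
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  arcs <- data.frame(from = arcFrom, to = arcTo, multiplicity = arcMult)
  new("AssemblyGraph", nodes = nodes, arcs = arcs,
      hashLength = hashLength, sequenceCount = seqCount,
      sequences = seqs)
}

#' Write a Velvet LastGraph
#'
#' Serializes an [AssemblyGraph-class] back to LastGraph layout (header,
#' NODE blocks with their two sequence lines, ARC records).
#' `readLastGraph(writeLastGraph(x))` is an identity on nodes, arcs and
#' stored sequences.
#'
#' @param asm an [AssemblyGraph-class].
#' @param file optional path (atomic write).
#' @return invisibly, the lines.
#' @export
writeLastGraph <- function(asm, file = NULL) {
  stopifnot(is(asm, "AssemblyGraph"))
  fmtNum <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  lines <- paste(fmtNum(c(nrow(asm@nodes), asm@sequenceCount, asm@hashLength)),
                 collapse = "\t")
  covCols <- grep("^cov", names(asm@nodes), value = TRUE)
  for (r in seq_len(nrow(asm@nodes))) {
    row <- asm@nodes[r, ]
    covs <- unlist(row[covCols], use.names = FALSE)
    covs <- covs[!is.na(covs)]
    lines <- c(lines,
               paste(c("NODE", fmtNum(row$id), fmtNum(row$length), fmtNum(covs)),
                     collapse = "\t"))
    sq <- asm@sequences[[as.character(row$id)]]
    if (is.null(sq)) sq <- c("", "")
    lines <- c(lines, sq)
  }
  a <- asm@arcs
  if (nrow(a)) {
    lines <- c(lines, paste("ARC", fmtNum(a$from), fmtNum(a$to),
                            fmtNum(a$multiplicity), sep = "\t"))
  }
  if (!is.null(file)) writeAtomic(lines, file)
  invisible(lines)
}
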