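## Cytoscape attribute files and tab-separated time-course tables.

#' Read a Cytoscape node/edge attribute file
#'
#' Format: the first line is the attribute name; every following non-blank
#' line is `id = value`. Duplicate ids keep the last value (files produced by
#' repeated exports routinely repeat entries). The table is numeric iff every
#' value parses as a number; otherwise all values are kept as text.
#'
#' @param file path or connection.
#' @param text alternatively the content as lines.
#' @return an [AttributeTable-class].
#' @examples
#' tab <- readNodeAttributes(text = c("Flux", "R1 = 2.5", "R2 = 0"))
#' tab@valueKind
#' @export
readNodeAttributes <- function(file = NULL, text = NULL) {
  lines <- sourceLines(file, text)
  if (!length(lines) || !nzchar(trimws(lines[1L]))) {
    formatError("attribute file line 1: missing attribute name header")
  }
  name <- trimws(lines[1L])
  ids <- character(); vals <- character()
  for (i in seq_along(lines)[-1L]) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^(.*?) = (.*)$", line))[[1L]]
    if (length(m) != 3L || !nzchar(trimws(m[2L]))) {
      formatError("attribute file line %d: expected 'id = value'", i)
    }
    ids <- c(ids, trimws(m[2L]))
    vals <- c(vals, trimws(m[3L]))
  }
  keep <- !duplicated(ids, fromLast = TRUE)
  ids <- ids[keep]; vals <- vals[keep]
  num <- suppressWarnings(as.numeric(vals))
  numeric <- length(vals) > 0L && !anyNA(num)
  entries <- if (numeric) setNames(num, ids) else setNames(vals, ids)
  new("AttributeTable", name = name, entries = entries,
      valueKind = if (numeric) "number" else "text")
}

#' Build an attribute table in code
#'
#' @param name attribute name.
#' @param entries named vector (numeric or character), names are element ids.
#' @return an [AttributeTable-class].
#' @export
attributeTable <- function(name, entries) {
  kind <- if (is.numeric(entries)) "number" else "text"
  if (kind == "text") entries <- setNames(as.character(entries), names(entries))
  new("AttributeTable", name = name, entries = entries, valueKind = kind)
}

#' Read a tab-separated time-course table
#'
#' Header: `id<TAB>frame1<TAB>frame2...`; one row per element with exactly
#' one numeric value per frame. Frame order is preserved; a ragged row (or a
#' non-numeric cell) is a format error naming the offending row.
#'
#' @param file path or connection.
#' @param text alternatively the content as lines.
#' @return a [TimeSeriesTable-class].
#' @export
readTimeSeries <- function(file = NULL, text = NULL) {
  lines <- sourceLines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) formatError("time-course table: empty input")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    formatError("time-course table line 1: header needs id and frame columns")
  }
  frames <- header[-1L]
  if (anyDuplicated(frames)) {
    formatError("time-course table: duplicate frame label '%s'",
                frames[duplicated(frames)][1L])
  }
  nf <- length(frames)
  rows <- lapply(lines[-1L], function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  ids <- character(length(rows))
  values <- matrix(NA_real_, nrow = length(rows), ncol = nf)
  for (r in seq_along(rows)) {
    toks <- rows[[r]]
    id <- if (length(toks)) toks[1L] else ""
    if (length(toks) != nf + 1L) {
      formatError("time-course row '%s': expected %d value cells, got %d",
                  id, nf, length(toks) - 1L)
    }
    v <- suppressWarnings(as.numeric(toks[-1L]))
    if (anyNA(v)) formatError("time-course row '%s': non-numeric value", id)
    ids[r] <- id
    values[r, ] <- v
  }
  keep <- !duplicated(ids, fromLast = TRUE)
  values <- values[keep, , drop = FALSE]
  rownames(values) <- ids[keep]
  colnames(values) <- frames
  new("TimeSeriesTable", frameLabels = frames, values = values)
}

#' Write an attribute table / a time-course table
#'
#' Inverse of [readNodeAttributes()] and [readTimeSeries()].
#'
#' @param table an [AttributeTable-class] or [TimeSeriesTable-class].
#' @param file optional path (atomic write).
#' @return invisibly, the lines.
#' @export
writeNodeAttributes <- function(table, file = NULL) {
  stopifnot(is(table, "AttributeTable"))
  lines <- c(table@name,
             sprintf("%s = %s", names(table@entries),
                     as.character(table@entries)))
  if (!is.null(file)) writeAtomic(lines, file)
  invisible(lines)
}

#' @rdname writeNodeAttributes
#' @param idColumn header label of the id column.
#' @export
writeTimeSeries <- function(table, file = NULL, idColumn = "id") {
  stopifnot(is(table, "TimeSeriesTable"))
  v <- table@values
  body <- vapply(seq_len(nrow(v)), function(r) {
    paste(c(rownames(v)[r], format(v[r, ], trim = TRUE, digits = 15)),
          collapse = "\t")
  }, character(1))
  lines <- c(paste(c(idColumn, table@frameLabels), collapse = "\t"), body)
  if (!is.null(file)) writeAtomic(lines, file)
  invisible(lines)
}
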