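#' @keywords internal
"_PACKAGE"

#' @useDynLib netscene3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new setClass setGeneric setMethod setValidity validObject is slot
#' @importFrom stats runif rlnorm aggregate setNames
#' @importFrom utils head tail
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific sub-seed; kept inside 32-bit integer range.
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * (as.numeric(stream) + 1)) %% 2147483647)
}

## Locale-independent (C collation) string sort/order, used everywhere identity
## or determinism depends on ordering.
idSort <- function(x) x[order(x, method = "radix")]
idOrder <- function(...) order(..., method = "radix")

## Stop with a classed condition so callers/tests can distinguish error kinds.
nsStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "netscene3dError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

formatError  <- function(fmt, ...) nsStop("netscene3dFormatError", fmt, ...)
lookupError  <- function(fmt, ...) nsStop("netscene3dLookupError", fmt, ...)
paramError   <- function(fmt, ...) nsStop("netscene3dParameterError", fmt, ...)
configError  <- function(fmt, ...) nsStop("netscene3dConfigError", fmt, ...)
numericError <- function(fmt, ...) nsStop("netscene3dNumericError", fmt, ...)
syncError    <- function(fmt, ...) nsStop("netscene3dSyncError", fmt, ...)

## Read lines from a file/connection or from a `text` argument (character
## vector of lines or a single string with embedded newlines).
sourceLines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    }
    return(sub("\r$", "", text))
  }
  if (is.null(file)) paramError("either 'file' or 'text' must be supplied")
  sub("\r$", "", readLines(file, warn = FALSE))
}

## Write lines atomically: write to a temp file in the same directory, then
## rename over the target, so a failed run never leaves a partial file.
writeAtomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
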