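## Internal helpers: classed conditions and small input checks.

.err <- function(subclass, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(paste0("tfinfluence_", subclass), "tfinfluence_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

.usageError  <- function(msg, ...) .err("usage_error", msg, ...)
.formatError <- function(msg, ...) .err("format_error", msg, ...)
.dataError   <- function(msg, ...) .err("data_error", msg, ...)
.lookupError <- function(msg, ...) .err("lookup_error", msg, ...)
.configError <- function(msg, ...) .err("config_error", msg, ...)

.trimws1 <- function(x) trimws(as.character(x))

## Gene symbols: non-empty after whitespace trimming, never NA.
.checkSymbols <- function(x, what = "gene symbol") {
  x <- .trimws1(x)
  bad <- is.na(x) | !nzchar(x)
  if (any(bad))
    .dataError(sprintf("invalid %s at position(s) %s: empty or NA",
                       what, paste(which(bad), collapse = ", ")))
  x
}

## Format a weight as decimal text with 9 significant digits ('.' decimal mark).
.fmtWeight <- function(w) sprintf("%.9g", w)

## Canonical edge-table ordering: lexicographic by (source, target), C locale.
.canonicalEdges <- function(df) {
  o <- order(df$source, df$target, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}
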