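#' Edge-table layout specification
#'
#' Describes how to read a TF-target interaction table: which columns hold
#' the source and target symbols, and whether the interaction carries a
#' numeric weight (Z-score style, FANTOM4-like tables) or a categorical
#' effect (RegulonDB-like tables: activation / repression / dual). Exactly
#' one of `weight` / `effect` may be given.
#'
#' @param source,target mandatory column names for the gene symbols.
#' @param weight column name of the numeric interaction strength, or `NULL`.
#' @param effect column name of the categorical effect, or `NULL`. Values
#'   `activation`/`positive` map to weight +1, `repression`/`negative` to
#'   -1 and `dual` to 0 (a dual edge counts toward degrees but is neutral in
#'   sign-mode polarity).
#' @param promoter optional promoter-identifier column.
#' @param sep field separator (default tab).
#' @param comment comment-line prefix (default `#`).
#' @return an `edgeTableSpec` list. `fantomSpec()` and `regulondbSpec()` are
#'   ready-made layouts for the two table styles above.
#' @export
edgeTableSpec <- function(source = "source", target = "target",
                          weight = "weight", effect = NULL,
                          promoter = NULL, sep = "\t", comment = "#") {
  if (is.null(weight) == is.null(effect))
    .usageError("exactly one of 'weight' and 'effect' must be given")
  structure(list(source = source, target = target, weight = weight,
                 effect = effect, promoter = promoter,
                 sep = sep, comment = comment),
            class = "edgeTableSpec")
}

#' @rdname edgeTableSpec
#' @export
fantomSpec <- function() edgeTableSpec(promoter = "promoter")

#' @rdname edgeTableSpec
#' @export
regulondbSpec <- function() edgeTableSpec(weight = NULL, effect = "effect")

.effectMap <- c(activation = 1, positive = 1, "+" = 1,
                repression = -1, negative = -1, "-" = -1,
                dual = 0)

#' Read an interaction table into a stream of signed interaction records
#'
#' Every data row becomes one record (duplicates per gene pair are kept:
#' multiplicity lives in the ingestion stream and is resolved by
#' [addInteractions()]'s max rule). Categorical effects are materialised to
#' weights +1 / -1 / 0 on the way in.
#'
#' @param path path to a delimited text file with a header row.
#' @param spec an [edgeTableSpec()].
#' @return data.frame with columns `source`, `target`, `weight` and, when the
#'   layout names a promoter column, `promoter`.
#' @export
readEdgeTable <- function(path, spec = edgeTableSpec()) {
  if (!inherits(spec, "edgeTableSpec"))
    .usageError("spec must be an edgeTableSpec()")
  if (!file.exists(path))
    .usageError(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = spec$sep, header = TRUE,
                          comment.char = spec$comment, quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  valueCol <- if (is.null(spec$weight)) spec$effect else spec$weight
  need <- c(spec$source, spec$target, valueCol)
  missing <- setdiff(need, names(df))
  if (length(missing))
    .formatError(sprintf("%s: missing mandatory column(s): %s",
                         path, paste(missing, collapse = ", ")))
  src <- .trimws1(df[[spec$source]])
  tgt <- .trimws1(df[[spec$target]])
  badRow <- which(is.na(src) | !nzchar(src) | is.na(tgt) | !nzchar(tgt))
  if (length(badRow))
    .dataError(sprintf("%s: missing source/target symbol at data row(s) %s",
                       path, paste(badRow, collapse = ", ")), rows = badRow)
  if (is.null(spec$weight)) {
    eff <- tolower(.trimws1(df[[spec$effect]]))
    w <- unname(.effectMap[eff])
    badRow <- which(is.na(w))
    if (length(badRow))
      .dataError(sprintf(
        "%s: unrecognised effect %s at data row(s) %s (expected activation/repression/dual)",
        path, paste(sQuote(df[[spec$effect]][badRow]), collapse = ", "),
        paste(badRow, collapse = ", ")), rows = badRow)
  } else {
    w <- suppressWarnings(as.numeric(df[[spec$weight]]))
    badRow <- which(!is.finite(w))
    if (length(badRow))
      .dataError(sprintf("%s: unparseable weight %s at data row(s) %s",
                         path,
                         paste(sQuote(df[[spec$weight]][badRow]), collapse = ", "),
                         paste(badRow, collapse = ", ")), rows = badRow)
  }
  out <- data.frame(source = src, target = tgt, weight = w,
                    stringsAsFactors = FALSE)
  if (!is.null(spec$promoter) && spec$promoter %in% names(df))
    out$promoter <- .trimws1(df[[spec$promoter]])
  out
}
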