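#' EdgeProvider: an abstract queryable edge database
#'
#' The seam between the breadth-first [crawl()] and whatever backs the
#' interaction data — here always an in-memory mock built from a record set
#' ([asProvider()]), but the same two-query contract the FANTOM4 EdgeExpress
#' database exposes gene by gene:
#' `regulatorsOf(provider, gene)` lists `(symbol, weight)` pairs for the
#' genes regulating `gene`, and `targetsOf(provider, gene)` those it
#' regulates. Duplicate pairs with different weights (promoter-level
#' records) may be returned; queries are pure within a session and every
#' symbol returned is itself queryable.
#'
#' @slot regulators function(gene) -> data.frame(symbol, weight).
#' @slot targets function(gene) -> data.frame(symbol, weight).
#' @slot calls environment holding the query counter (`n`).
#'
#' @param regulators,targets backing functions, each taking one gene symbol
#'   and returning a data.frame with columns `symbol` and `weight`.
#' @param provider an `EdgeProvider`.
#' @param gene a gene symbol.
#' @return `regulatorsOf()`/`targetsOf()` return a data.frame with columns
#'   `symbol`, `weight` (zero rows when the gene has none);
#'   `providerCalls()` the total number of queries answered so far.
#' @aliases regulatorsOf targetsOf providerCalls
#' @export edgeProvider
#' @exportClass EdgeProvider
setClass("EdgeProvider",
  representation(regulators = "function", targets = "function",
                 calls = "environment"))

edgeProvider <- function(regulators, targets) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  new("EdgeProvider", regulators = regulators, targets = targets,
      calls = calls)
}

.emptyAnswer <- data.frame(symbol = character(0), weight = numeric(0),
                           stringsAsFactors = FALSE)

.normalizeAnswer <- function(res, gene, what) {
  if (is.null(res) || !nrow(res <- as.data.frame(res))) return(.emptyAnswer)
  if (!all(c("symbol", "weight") %in% names(res)))
    .dataError(sprintf("provider answer for %s of '%s' lacks symbol/weight",
                       what, gene))
  data.frame(symbol = as.character(res$symbol),
             weight = as.numeric(res$weight), stringsAsFactors = FALSE)
}

#' @rdname EdgeProvider-class
setMethod("regulatorsOf", "EdgeProvider", function(provider, gene) {
  provider@calls$n <- provider@calls$n + 1L
  .normalizeAnswer(provider@regulators(gene), gene, "regulators")
})

#' @rdname EdgeProvider-class
setMethod("targetsOf", "EdgeProvider", function(provider, gene) {
  provider@calls$n <- provider@calls$n + 1L
  .normalizeAnswer(provider@targets(gene), gene, "targets")
})

#' @rdname EdgeProvider-class
setMethod("providerCalls", "EdgeProvider",
          function(provider) provider@calls$n)

setMethod("show", "EdgeProvider", function(object) {
  cat("EdgeProvider;", providerCalls(object), "queries answered\n")
  invisible(NULL)
})

#' Wrap a set of interaction records as an EdgeProvider
#'
#' Builds an in-memory provider answering the two crawl queries from an
#' interaction record set, duplicates included, answers sorted
#' lexicographically by symbol (then weight) so traversal order is
#' deterministic. Genes absent from the records are queryable and answer
#' with empty tables.
#'
#' @param records data.frame with columns `source`, `target`, `weight`.
#' @return an `EdgeProvider`.
#' @examples
#' recs <- data.frame(source = c("A", "A"), target = c("B", "B"),
#'                    weight = c(0.5, 2))
#' p <- asProvider(recs)
#' targetsOf(p, "A")
#' @export
asProvider <- function(records) {
  records <- .validateRecords(records)
  bySource <- new.env(parent = emptyenv(), hash = TRUE)
  byTarget <- new.env(parent = emptyenv(), hash = TRUE)
  .stash <- function(env, key, df) {
    o <- order(df$symbol, df$weight, method = "radix")
    assign(key, df[o, , drop = FALSE], envir = env)
  }
  if (nrow(records)) {
    for (sp in split(records, records$source))
      .stash(bySource, sp$source[1L],
             data.frame(symbol = sp$target, weight = sp$weight,
                        stringsAsFactors = FALSE))
    for (sp in split(records, records$target))
      .stash(byTarget, sp$target[1L],
             data.frame(symbol = sp$source, weight = sp$weight,
                        stringsAsFactors = FALSE))
  }
  .answer <- function(env) function(gene) {
    gene <- .trimws1(gene)
    if (exists(gene, envir = env, inherits = FALSE))
      get(gene, envir = env, inherits = FALSE)
    else .emptyAnswer
  }
  edgeProvider(regulators = .answer(byTarget), targets = .answer(bySource))
}
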