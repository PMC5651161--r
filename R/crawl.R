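#' Breadth-first crawl of an edge database
#'
#' Starting from a seed gene, walks the provider breadth-first: a FIFO queue
#' of genes to explore and a registry of genes already seen. Each dequeued
#' gene is queried once for its regulators and once for its targets; every
#' interaction found is submitted through the network's max-weight rule, and
#' every newly seen symbol is enqueued. The crawl terminates when the queue
#' empties, having recovered exactly the weakly connected component of the
#' seed under the provider's union graph — identical, nodes, edges and
#' weights, to bulk-loading the same records. `crawlAll()` unions the crawls
#' from several seeds (a database may hold disconnected components no single
#' seed can reach).
#'
#' @param provider an [EdgeProvider][EdgeProvider-class].
#' @param seed,seeds gene symbol(s) to start from; each must be queryable.
#' @param aggregation duplicate-collapsing rule for the resulting network.
#' @return a `RegulatoryNetwork`. If a provider query fails, an error of
#'   class `tfinfluence_crawl_error` is signalled carrying the failing
#'   `symbol` and the `partial` network built so far.
#' @examples
#' recs <- data.frame(source = c("A", "B"), target = c("B", "C"), weight = 1)
#' net <- crawl(asProvider(recs), "C")
#' numEdges(net)   # 2: the whole component, crawled from a leaf
#' @export
crawl <- function(provider, seed, aggregation = c("signed-max", "abs-max")) {
  crawlAll(provider, seed, aggregation)
}

#' @rdname crawl
#' @export
crawlAll <- function(provider, seeds,
                     aggregation = c("signed-max", "abs-max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(provider, "EdgeProvider"))
  seeds <- unique(.checkSymbols(seeds, "seed symbol"))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  queue <- character(0)
  head <- 1L
  .enqueue <- function(sym) {
    fresh <- sym[!vapply(sym, exists, NA, envir = seen, inherits = FALSE)]
    for (s in fresh) assign(s, TRUE, envir = seen)
    queue <<- c(queue, fresh)
  }
  records <- vector("list", 0L)
  .partial <- function() {
    regulatoryNetwork(edges = do.call(rbind, records),
                      nodes = ls(seen), aggregation = aggregation)
  }
  .enqueue(seeds)
  while (head <= length(queue)) {
    gene <- queue[head]; head <- head + 1L
    ans <- tryCatch(
      list(reg = regulatorsOf(provider, gene),
           tgt = targetsOf(provider, gene)),
      error = function(e) {
        .err("crawl_error",
             sprintf("provider query failed for '%s': %s",
                     gene, conditionMessage(e)),
             symbol = gene, partial = .partial())
      })
    if (nrow(ans$reg))
      records[[length(records) + 1L]] <-
        data.frame(source = ans$reg$symbol, target = gene,
                   weight = ans$reg$weight, stringsAsFactors = FALSE)
    if (nrow(ans$tgt))
      records[[length(records) + 1L]] <-
        data.frame(source = gene, target = ans$tgt$symbol,
                   weight = ans$tgt$weight, stringsAsFactors = FALSE)
    .enqueue(unique(c(ans$reg$symbol, ans$tgt$symbol)))
  }
  .partial()
}
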