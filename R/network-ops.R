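## Graph-model operations: interaction submission with max-weight
## aggregation, degree accounting, and subnetwork extraction.

## Collapse a multiset of interaction records to one row per ordered pair.
## signed-max keeps the largest signed weight ("biggest value" read
## literally); abs-max keeps the largest |weight|, ties resolved toward the
## larger signed weight so the result never depends on submission order.
.aggregateRecords <- function(df, rule) {
  if (!nrow(df)) return(df)
  key <- paste0(df$source, "\r", df$target)
  rank1 <- if (rule == "abs-max") -abs(df$weight) else -df$weight
  o <- order(key, rank1, -df$weight, method = "radix")
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(key[o]), , drop = FALSE]
  .canonicalEdges(df)
}

.validateRecords <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(records)))
    .formatError("interaction records need columns source, target, weight")
  records$source <- .checkSymbols(records$source, "source symbol")
  records$target <- .checkSymbols(records$target, "target symbol")
  records$weight <- as.numeric(records$weight)
  if (any(!is.finite(records$weight)))
    .dataError(sprintf("non-finite interaction weight at record(s) %s",
                       paste(which(!is.finite(records$weight)), collapse = ", ")))
  records[c("source", "target", "weight")]
}

#' Submit interaction records to a network (max-weight aggregation)
#'
#' Multiple promoter-level records may exist for one ordered gene pair; a
#' `RegulatoryNetwork` stores a single edge per pair, carrying the maximum
#' over all submitted weights (the network's aggregation rule; signed maximum
#' by default). Submission is order-independent and idempotent: re-submitting
#' the stored weight changes nothing. Both endpoints are added as nodes if
#' absent.
#'
#' @param object a `RegulatoryNetwork`.
#' @param source,target gene symbols (non-empty strings; trimmed, matched
#'   case-sensitively).
#' @param weight finite interaction strength (Z-score scale).
#' @param promoter optional promoter identifier; carried by ingestion streams
#'   only, never stored on the network.
#' @param records a data.frame of interaction records with columns `source`,
#'   `target`, `weight` (extra columns are ignored).
#' @return the updated `RegulatoryNetwork`.
#' @examples
#' net <- regulatoryNetwork()
#' for (w in c(0.834, 4.857, 0.845))
#'   net <- addInteraction(net, "SOX2", "SRF", w)
#' edgeWeight(net, "SOX2", "SRF")   # 4.857
#' @rdname addInteraction
setMethod("addInteraction", "RegulatoryNetwork",
  function(object, source, target, weight, promoter = NA_character_) {
    if (length(source) != 1L || length(target) != 1L || length(weight) != 1L)
      .usageError("addInteraction() takes a single record; use addInteractions() for batches")
    addInteractions(object, data.frame(source = source, target = target,
                                       weight = weight,
                                       stringsAsFactors = FALSE))
  })

#' @rdname addInteraction
setMethod("addInteractions", "RegulatoryNetwork",
  function(object, records) {
    records <- .validateRecords(records)
    if (!nrow(records)) return(object)
    combined <- rbind(object@edges[c("source", "target", "weight")], records)
    object@edges <- .aggregateRecords(combined, object@aggregation)
    newGenes <- setdiff(unique(c(records$source, records$target)),
                        object@nodes)
    if (length(newGenes))
      object@nodes <- sort(c(object@nodes, newGenes), method = "radix")
    validObject(object)
    object
  })

#' Per-gene in- and out-degrees
#'
#' In-degree counts distinct regulators; out-degree counts distinct targets
#' (the network stores at most one edge per ordered pair, so these are plain
#' edge counts). A self-loop contributes one to each. The sums of in- and
#' out-degrees both equal the number of edges.
#'
#' @param object a `RegulatoryNetwork`.
#' @return data.frame with columns `gene`, `in_degree`, `out_degree`, one row
#'   per node, sorted by gene symbol.
#' @rdname degrees
setMethod("degrees", "RegulatoryNetwork", function(object) {
  genes <- sort(object@nodes, method = "radix")
  e <- object@edges
  out <- table(factor(e$source, levels = genes))
  inn <- table(factor(e$target, levels = genes))
  data.frame(gene = genes,
             in_degree = as.integer(inn),
             out_degree = as.integer(out),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' Extract the TF-only subnetwork
#'
#' Removes every effector gene — a gene with zero out-degree in the full
#' network — and keeps the subgraph induced by the remaining nodes (the
#' transcription factors). The pass is applied once, not iterated: membership
#' is decided by out-degree in the parent network, so a TF whose only targets
#' were effectors is kept even though it has no edges here.
#'
#' @param object a `RegulatoryNetwork`.
#' @return a new `RegulatoryNetwork`; the input is unmodified.
#' @rdname tfSubnetwork
setMethod("tfSubnetwork", "RegulatoryNetwork", function(object) {
  d <- degrees(object)
  keep <- d$gene[d$out_degree > 0L]
  .induce(object, keep, edgeFilter = function(e)
    e$source %in% keep & e$target %in% keep)
})

#' Subnetwork of the targets of a set of source genes
#'
#' Returns the subgraph over `sources` and their direct out-neighbours,
#' restricted to edges leaving a source (used e.g. to examine what the
#' top-k out-degree TFs jointly regulate).
#'
#' @param object a `RegulatoryNetwork`.
#' @param sources character vector of gene symbols present in the network.
#' @return a new `RegulatoryNetwork`.
#' @rdname targetSubnetwork
setMethod("targetSubnetwork", "RegulatoryNetwork", function(object, sources) {
  sources <- unique(.trimws1(sources))
  unknown <- setdiff(sources, object@nodes)
  if (length(unknown))
    .lookupError(sprintf("unknown source gene(s): %s",
                         paste(unknown, collapse = ", ")),
                 symbols = unknown)
  e <- object@edges
  outEdges <- e[e$source %in% sources, , drop = FALSE]
  keep <- unique(c(sources, outEdges$target))
  .induce(object, keep, edgeFilter = function(e) e$source %in% sources)
})

## Induced subgraph helper: node subset + edge predicate; annotations follow.
.induce <- function(object, keep, edgeFilter) {
  sub <- new("RegulatoryNetwork", aggregation = object@aggregation)
  sub@nodes <- sort(keep, method = "radix")
  e <- object@edges
  sub@edges <- .canonicalEdges(e[edgeFilter(e), , drop = FALSE])
  nd <- object@nodeData
  if (nrow(nd)) sub@nodeData <- nd[nd$gene %in% keep, , drop = FALSE]
  validObject(sub)
  sub
}

#' Summary counts of a regulatory network
#'
#' @param object a `RegulatoryNetwork`.
#' @return one-row data.frame: gene/edge counts, TF and effector counts, and
#'   positive/negative/neutral edge counts.
#' @export
networkSummary <- function(object) {
  stopifnot(is(object, "RegulatoryNetwork"))
  d <- degrees(object)
  w <- object@edges$weight
  data.frame(
    n_genes = numNodes(object),
    n_edges = numEdges(object),
    n_tf = sum(d$out_degree > 0L),
    n_effector = sum(d$out_degree == 0L),
    n_positive = sum(w > 0),
    n_negative = sum(w < 0),
    n_neutral = sum(w == 0),
    stringsAsFactors = FALSE
  )
}
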