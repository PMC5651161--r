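#' RegulatoryNetwork: a directed, signed, weighted gene-regulation graph
#'
#' The central data structure of the package. Nodes are genes (case-preserved
#' symbols, matched exactly after whitespace trimming); edges are directed
#' regulatory interactions carrying one real-valued weight per ordered
#' (source, target) pair. Interaction strengths are Z-scores combining
#' experiment and binding-site prediction; positive weights mean activation,
#' negative weights repression. When several promoter-level records exist for
#' the same pair, only one edge is stored: the one selected by the network's
#' aggregation rule (see [addInteraction()]).
#'
#' @slot nodes character vector of unique gene symbols.
#' @slot edges data.frame with columns `source`, `target`, `weight`; at most
#'   one row per ordered pair, kept sorted lexicographically by
#'   (source, target).
#' @slot nodeData data.frame of per-gene annotations (column `gene` plus
#'   arbitrary annotation columns, e.g. `avg_transcript_count`); may be empty.
#' @slot aggregation `"signed-max"` (default) or `"abs-max"`: the rule used to
#'   collapse duplicate records for one ordered pair.
#'
#' @param edges optional data.frame of interaction records (columns `source`,
#'   `target`, `weight`) submitted through the aggregation rule.
#' @param nodes optional character vector of gene symbols to include even if
#'   they carry no edge.
#' @param nodeData optional annotation data.frame (must contain a `gene`
#'   column whose values are nodes of the network).
#' @param aggregation aggregation rule, `"signed-max"` or `"abs-max"`.
#' @param object a `RegulatoryNetwork`.
#'
#' @return `regulatoryNetwork()` returns a `RegulatoryNetwork`. `geneIds()`
#'   returns the sorted character vector of gene symbols; `edgeTable()` the
#'   canonical edge data.frame; `numNodes()`/`numEdges()` integer counts;
#'   `aggregationRule()` the rule string; `nodeAnnotations()` the annotation
#'   data.frame.
#'
#' @examples
#' net <- regulatoryNetwork()
#' net <- addInteraction(net, "SOX2", "SRF", 4.857)
#' net <- addInteraction(net, "SOX2", "SRF", 0.834)
#' edgeTable(net)
#'
#' @aliases geneIds edgeTable numNodes numEdges aggregationRule
#'   nodeAnnotations
#' @export regulatoryNetwork
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    nodeData = "data.frame",
    aggregation = "character"
  ),
  prototype(
    nodes = character(0),
    edges = data.frame(source = character(0), target = character(0),
                       weight = numeric(0), stringsAsFactors = FALSE),
    nodeData = data.frame(gene = character(0), stringsAsFactors = FALSE),
    aggregation = "signed-max"
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character(0)
  n <- object@nodes
  if (anyNA(n) || any(!nzchar(n)))
    msg <- c(msg, "node ids must be non-empty, non-NA strings")
  if (anyDuplicated(n))
    msg <- c(msg, "node ids must be unique")
  e <- object@edges
  if (!all(c("source", "target", "weight") %in% names(e))) {
    msg <- c(msg, "edges must have columns source, target, weight")
  } else {
    if (!all(e$source %in% n) || !all(e$target %in% n))
      msg <- c(msg, "every edge endpoint must be a node")
    if (any(!is.finite(e$weight)))
      msg <- c(msg, "edge weights must be finite")
    if (anyDuplicated(paste0(e$source, "\r", e$target)))
      msg <- c(msg, "at most one edge per ordered (source, target) pair")
  }
  if (!(length(object@aggregation) == 1L &&
        object@aggregation %in% c("signed-max", "abs-max")))
    msg <- c(msg, "aggregation must be 'signed-max' or 'abs-max'")
  nd <- object@nodeData
  if (nrow(nd) > 0L) {
    if (!"gene" %in% names(nd))
      msg <- c(msg, "nodeData must have a 'gene' column")
    else if (anyDuplicated(nd$gene) || !all(nd$gene %in% n))
      msg <- c(msg, "nodeData genes must be unique network nodes")
  }
  if (length(msg)) msg else TRUE
})

regulatoryNetwork <- function(edges = NULL, nodes = character(0),
                              nodeData = NULL,
                              aggregation = c("signed-max", "abs-max")) {
  aggregation <- match.arg(aggregation)
  net <- new("RegulatoryNetwork", aggregation = aggregation)
  if (length(nodes)) {
    nodes <- unique(.checkSymbols(nodes, "node id"))
    net@nodes <- sort(nodes, method = "radix")
  }
  if (!is.null(edges) && nrow(edges)) net <- addInteractions(net, edges)
  if (!is.null(nodeData)) {
    nodeData <- as.data.frame(nodeData, stringsAsFactors = FALSE)
    net@nodeData <- nodeData
    validObject(net)
  }
  net
}

#' @rdname RegulatoryNetwork-class
setMethod("geneIds", "RegulatoryNetwork", function(object) object@nodes)

#' @rdname RegulatoryNetwork-class
setMethod("edgeTable", "RegulatoryNetwork", function(object) object@edges)

#' @rdname RegulatoryNetwork-class
setMethod("numNodes", "RegulatoryNetwork",
          function(object) length(object@nodes))

#' @rdname RegulatoryNetwork-class
setMethod("numEdges", "RegulatoryNetwork",
          function(object) nrow(object@edges))

#' @rdname RegulatoryNetwork-class
setMethod("aggregationRule", "RegulatoryNetwork",
          function(object) object@aggregation)

#' @rdname RegulatoryNetwork-class
setMethod("nodeAnnotations", "RegulatoryNetwork",
          function(object) object@nodeData)

setMethod("show", "RegulatoryNetwork", function(object) {
  d <- degrees(object)
  nTF <- sum(d$out_degree > 0L)
  cat("RegulatoryNetwork with", numNodes(object), "genes and",
      numEdges(object), "interactions\n")
  cat("  TFs (out-degree > 0):", nTF,
      " effectors:", numNodes(object) - nTF, "\n")
  cat("  aggregation rule:", object@aggregation, "\n")
  if (numEdges(object)) {
    w <- object@edges$weight
    cat(sprintf("  weights: %d positive, %d negative, %d neutral\n",
                sum(w > 0), sum(w < 0), sum(w == 0)))
  }
  invisible(NULL)
})

#' Look up the weight of a single stored edge
#'
#' @param object a `RegulatoryNetwork`.
#' @param source,target gene symbols of the ordered pair.
#' @return the stored edge weight, or `NA` when no such edge exists.
#' @export
edgeWeight <- function(object, source, target) {
  stopifnot(is(object, "RegulatoryNetwork"))
  e <- object@edges
  i <- which(e$source == source & e$target == target)
  if (length(i)) e$weight[i] else NA_real_
}
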