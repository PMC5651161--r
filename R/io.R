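#' Write and read networks in standard graph formats
#'
#' `writeNetwork()` serialises a `RegulatoryNetwork`; `readNetwork()` loads
#' one back. Three formats are supported:
#' \describe{
#'   \item{`tsv`}{edge list, UTF-8, tab-separated, header
#'     `source\\ttarget\\tweight`, one row per edge, sorted lexicographically
#'     by (source, target); weights printed as decimal text with 9
#'     significant digits. Lines starting `#` are comments. The round trip
#'     write-then-read is the identity on networks whose weights carry at
#'     most 9 significant digits (everything the package itself produces).}
#'   \item{`sif`}{Cytoscape simple-interaction format,
#'     `source\\treg\\ttarget`. Weights are not representable; reading a SIF
#'     assigns weight 1 to every edge.}
#'   \item{`graphml`}{via \pkg{igraph}; edge attribute `weight` (double),
#'     node annotation columns (e.g. `avg_transcript_count`) stored as node
#'     attributes.}
#' }
#'
#' @param object a `RegulatoryNetwork`.
#' @param path file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param aggregation aggregation rule for the network built on read.
#' @return `writeNetwork()` returns `path` invisibly; `readNetwork()` a
#'   `RegulatoryNetwork`.
#' @export
writeNetwork <- function(object, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(is(object, "RegulatoryNetwork"))
  format <- .matchFormat(format)
  e <- edgeTable(object)
  switch(format,
    tsv = {
      lines <- c("source\ttarget\tweight",
                 if (nrow(e)) paste(e$source, e$target,
                                    .fmtWeight(e$weight), sep = "\t"))
      writeLines(lines, path, useBytes = TRUE)
    },
    sif = {
      writeLines(if (nrow(e)) paste(e$source, "reg", e$target, sep = "\t")
                 else character(0), path, useBytes = TRUE)
    },
    graphml = {
      g <- .asIgraph(object)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path, format = c("tsv", "sif", "graphml"),
                        aggregation = c("signed-max", "abs-max")) {
  format <- .matchFormat(format)
  aggregation <- match.arg(aggregation)
  if (!file.exists(path)) .usageError(sprintf("no such file: %s", path))
  switch(format,
    tsv = {
      recs <- readEdgeTable(path, edgeTableSpec())
      regulatoryNetwork(edges = recs, aggregation = aggregation)
    },
    sif = {
      lines <- readLines(path)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines))
        return(regulatoryNetwork(aggregation = aggregation))
      parts <- strsplit(lines, "[\t ]+")
      bad <- which(vapply(parts, length, 1L) < 3L)
      if (length(bad))
        .formatError(sprintf("%s: malformed SIF line(s) %s", path,
                             paste(bad, collapse = ", ")))
      recs <- data.frame(source = vapply(parts, `[[`, "", 1L),
                         target = vapply(parts, `[[`, "", 3L),
                         weight = 1, stringsAsFactors = FALSE)
      regulatoryNetwork(edges = recs, aggregation = aggregation)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      .fromIgraph(g, aggregation)
    })
}

.matchFormat <- function(format) {
  format <- format[1L]
  if (!format %in% c("tsv", "sif", "graphml"))
    .usageError(sprintf("unknown network format: %s", format))
  format
}

## igraph conversion (GraphML backend and independent degree cross-checks).
.asIgraph <- function(object) {
  vertices <- data.frame(name = geneIds(object), stringsAsFactors = FALSE)
  nd <- nodeAnnotations(object)
  if (nrow(nd)) {
    ann <- nd[match(vertices$name, nd$gene), setdiff(names(nd), "gene"),
              drop = FALSE]
    vertices <- cbind(vertices, ann)
  }
  igraph::graph_from_data_frame(edgeTable(object), directed = TRUE,
                                vertices = vertices)
}

.fromIgraph <- function(g, aggregation = "signed-max") {
  e <- igraph::as_data_frame(g, what = "edges")
  v <- igraph::as_data_frame(g, what = "vertices")
  recs <- data.frame(source = e$from, target = e$to,
                     weight = if ("weight" %in% names(e)) e$weight else 1,
                     stringsAsFactors = FALSE)
  nd <- NULL
  extra <- setdiff(names(v), "name")
  if (length(extra)) {
    nd <- data.frame(gene = v$name, v[, extra, drop = FALSE],
                     stringsAsFactors = FALSE)
    names(nd) <- c("gene", extra)
  }
  net <- regulatoryNetwork(edges = recs, nodes = v$name,
                           aggregation = aggregation)
  if (!is.null(nd)) {
    net@nodeData <- nd
    validObject(net)
  }
  net
}
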