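## Pipeline entry points: each run* function is one step of the analysis,
## reading/writing plain-text artifacts in an output directory. The
## command-line script inst/scripts/tfnet.R is a thin dispatcher over these.

.ensureDir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

.writeTSV <- function(df, path, ri = NULL) {
  for (col in ri) df[[col]] <- .fmtWeight(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.loadInput <- function(input, format, aggregation = "signed-max") {
  switch(format,
    "fantom-tsv" = regulatoryNetwork(
      edges = readEdgeTable(input, fantomSpec()), aggregation = aggregation),
    "regulondb-tsv" = regulatoryNetwork(
      edges = readEdgeTable(input, regulondbSpec()), aggregation = aggregation),
    "tsv" = readNetwork(input, "tsv", aggregation),
    "sif" = readNetwork(input, "sif", aggregation),
    "graphml" = readNetwork(input, "graphml", aggregation),
    .usageError(sprintf("unknown input format: %s", format)))
}

#' Build a network from an interaction table and write it with a summary
#'
#' @param input path to the interaction table (or network file).
#' @param format one of `"fantom-tsv"` (source/target/weight, optional
#'   promoter column, duplicates allowed), `"regulondb-tsv"`
#'   (source/target/effect with categorical
#'   activation/repression/dual), `"tsv"`, `"sif"`, `"graphml"`.
#' @param outDir output directory (created if needed).
#' @param aggregation duplicate-collapsing rule, `"signed-max"` or
#'   `"abs-max"`.
#' @return invisibly, a list with the built `network` and its `summary` row.
#'   Writes `network.tsv`, `network.graphml` and `summary.tsv`.
#' @export
runBuild <- function(input, format = "fantom-tsv", outDir = ".",
                     aggregation = c("signed-max", "abs-max")) {
  aggregation <- match.arg(aggregation)
  net <- .loadInput(input, format, aggregation)
  .ensureDir(outDir)
  writeNetwork(net, file.path(outDir, "network.tsv"), "tsv")
  writeNetwork(net, file.path(outDir, "network.graphml"), "graphml")
  s <- networkSummary(net)
  .writeTSV(s, file.path(outDir, "summary.tsv"))
  invisible(list(network = net, summary = s))
}

#' Relative-influence report: full table plus top/bottom k
#'
#' @param network a `RegulatoryNetwork`, or a path to a network edge-TSV.
#' @param epsilon,k,tfOnly see [influenceTable()] and [topBottom()].
#' @param outDir output directory.
#' @return invisibly, list(table, top, bottom). Writes `influence.tsv`,
#'   `influence_top.tsv`, `influence_bottom.tsv` (RI printed with 9
#'   significant digits).
#' @export
runRI <- function(network, epsilon = 1e-3, k = 10, tfOnly = TRUE,
                  outDir = ".") {
  net <- if (is(network, "RegulatoryNetwork")) network
         else readNetwork(network, "tsv")
  tab <- influenceTable(net, epsilon = epsilon)
  tb <- topBottom(tab, k = k, restrictToTFs = tfOnly)
  .ensureDir(outDir)
  .writeTSV(tab, file.path(outDir, "influence.tsv"), ri = "ri")
  .writeTSV(tb$top, file.path(outDir, "influence_top.tsv"), ri = "ri")
  .writeTSV(tb$bottom, file.path(outDir, "influence_bottom.tsv"), ri = "ri")
  invisible(list(table = tab, top = tb$top, bottom = tb$bottom))
}

#' Polarity report: per-TF scores plus top activators and repressors
#'
#' @param network a `RegulatoryNetwork` or a path to a network edge-TSV.
#' @param mode `"sign"` (default) or `"weight"`; both score columns are
#'   written, the label follows the chosen mode.
#' @param k rows in each extreme table.
#' @param outDir output directory.
#' @return invisibly, list(table, activators, repressors). Writes
#'   `polarity.tsv`, `top_activators.tsv`, `top_repressors.tsv`.
#' @export
runPolarity <- function(network, mode = c("sign", "weight"), k = 3,
                        outDir = ".") {
  mode <- match.arg(mode)
  net <- if (is(network, "RegulatoryNetwork")) network
         else readNetwork(network, "tsv")
  tab <- polarityTable(net, mode)
  k <- min(k, nrow(tab))
  act <- tab[seq_len(k), , drop = FALSE]
  rep_ <- tab[rev(seq.int(nrow(tab) - k + 1L, length.out = k)), , drop = FALSE]
  rownames(act) <- rownames(rep_) <- NULL
  .ensureDir(outDir)
  .writeTSV(tab, file.path(outDir, "polarity.tsv"), ri = "score_weight")
  .writeTSV(act, file.path(outDir, "top_activators.tsv"), ri = "score_weight")
  .writeTSV(rep_, file.path(outDir, "top_repressors.tsv"), ri = "score_weight")
  invisible(list(table = tab, activators = act, repressors = rep_))
}

#' Extract and write the TF-only subnetwork
#'
#' @param network a `RegulatoryNetwork` or a path to a network edge-TSV.
#' @param outDir output directory.
#' @return invisibly the TF subnetwork. Writes `tf_subnetwork.tsv` and
#'   `tf_subnetwork.graphml`.
#' @export
runTFSubnet <- function(network, outDir = ".") {
  net <- if (is(network, "RegulatoryNetwork")) network
         else readNetwork(network, "tsv")
  sub <- tfSubnetwork(net)
  .ensureDir(outDir)
  writeNetwork(sub, file.path(outDir, "tf_subnetwork.tsv"), "tsv")
  writeNetwork(sub, file.path(outDir, "tf_subnetwork.graphml"), "graphml")
  invisible(sub)
}

#' Generate a synthetic instance and write its records and manifest
#'
#' Identical config and seed produce byte-identical files.
#'
#' @param config a [generatorConfig()].
#' @param outDir output directory.
#' @return invisibly the [simulateNetwork()] result. Writes `edges.tsv`
#'   (record stream with promoter column) and `manifest.tsv`.
#' @export
runSimulate <- function(config = generatorConfig(), outDir = ".") {
  sim <- simulateNetwork(config)
  .ensureDir(outDir)
  rec <- sim$records
  rec$weight <- .fmtWeight(rec$weight)
  utils::write.table(rec, file.path(outDir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  .writeTSV(sim$manifest, file.path(outDir, "manifest.tsv"), ri = "ri_true")
  invisible(sim)
}

#' Run the full pipeline into one report directory
#'
#' Builds (or simulates) the network, then writes the influence, polarity
#' and TF-subnetwork reports plus a run log recording the effective
#' configuration.
#'
#' @param input path to an interaction table, or `NULL` to simulate.
#' @param format input format, see [runBuild()].
#' @param config [generatorConfig()] used when `input` is `NULL`.
#' @param epsilon,k,mode,aggregation pipeline parameters.
#' @param outDir report directory.
#' @return invisibly, list(network, summary, influence, polarity).
#' @export
runReport <- function(input = NULL, format = "fantom-tsv",
                      config = generatorConfig(), epsilon = 1e-3, k = 10,
                      mode = "sign",
                      aggregation = c("signed-max", "abs-max"),
                      outDir = ".") {
  aggregation <- match.arg(aggregation)
  .ensureDir(outDir)
  if (is.null(input)) {
    sim <- runSimulate(config, outDir)
    net <- regulatoryNetwork(edges = sim$records,
                             nodes = sim$manifest$gene,
                             aggregation = aggregation)
    writeNetwork(net, file.path(outDir, "network.tsv"), "tsv")
    writeNetwork(net, file.path(outDir, "network.graphml"), "graphml")
    s <- networkSummary(net)
    .writeTSV(s, file.path(outDir, "summary.tsv"))
    built <- list(network = net, summary = s)
  } else {
    built <- runBuild(input, format, outDir, aggregation)
  }
  ri <- runRI(built$network, epsilon = epsilon, k = k, outDir = outDir)
  pol <- runPolarity(built$network, mode = mode, k = k, outDir = outDir)
  runTFSubnet(built$network, outDir = outDir)
  log <- c(
    sprintf("tfinfluence %s | R %s.%s",
            as.character(utils::packageVersion("tfinfluence")),
            R.version$major, R.version$minor),
    sprintf("input: %s", if (is.null(input))
      sprintf("simulated (seed %d)", config$seed) else input),
    sprintf("format: %s", format),
    sprintf("aggregation: %s", aggregation),
    sprintf("epsilon: %g", epsilon),
    sprintf("polarity mode: %s", mode),
    sprintf("k: %d", as.integer(k)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(list(network = built$network, summary = built$summary,
                 influence = ri, polarity = pol))
}
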