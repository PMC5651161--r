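writeTempTable <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a weighted table streams one record per row; aggregation collapses duplicates", {
  path <- writeTempTable(c(
    "source\ttarget\tweight\tpromoter",
    "SOX2\tSRF\t4.857\tp1",
    "SOX2\tSRF\t0.834\tp2",
    "SOX2\tSRF\t0.845\tp3"))
  recs <- readEdgeTable(path, fantomSpec())
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$promoter, c("p1", "p2", "p3"))
  net <- addInteractions(regulatoryNetwork(), recs)
  expect_identical(numEdges(net), 1L)
  expect_identical(edgeWeight(net, "SOX2", "SRF"), 4.857)
})

test_that("categorical effects materialise to +1 / -1 / 0 weights", {
  path <- writeTempTable(c(
    "source\ttarget\teffect",
    "Fis\tcrp\trepression",
    "Crp\tfis\tactivation",
    "Fnr\tnarL\tdual"))
  recs <- readEdgeTable(path, regulondbSpec())
  expect_identical(recs$weight, c(-1, 1, 0))
})

test_that("an empty table with a valid header yields an empty stream", {
  path <- writeTempTable("source\ttarget\tweight")
  recs <- readEdgeTable(path)
  expect_identical(nrow(recs), 0L)
  expect_identical(names(recs), c("source", "target", "weight"))
})

test_that("reader errors carry file context and row numbers", {
  missingCol <- writeTempTable(c("source\tweight", "A\t1"))
  expect_error(readEdgeTable(missingCol), class = "tfinfluence_format_error")

  badWeight <- writeTempTable(c("source\ttarget\tweight",
                                "A\tB\t1.5", "C\tD\toops"))
  err <- tryCatch(readEdgeTable(badWeight), error = function(e) e)
  expect_s3_class(err, "tfinfluence_data_error")
  expect_match(conditionMessage(err), "row\\(s\\) 2")

  emptySym <- writeTempTable(c("source\ttarget\tweight", "A\tB\t1", "\tD\t2"))
  err <- tryCatch(readEdgeTable(emptySym), error = function(e) e)
  expect_s3_class(err, "tfinfluence_data_error")
  expect_match(conditionMessage(err), "row\\(s\\) 2")

  badEffect <- writeTempTable(c("source\ttarget\teffect", "A\tB\tmaybe"))
  expect_error(readEdgeTable(badEffect, regulondbSpec()),
               class = "tfinfluence_data_error")

  expect_error(edgeTableSpec(weight = "w", effect = "e"),
               class = "tfinfluence_usage_error")
  expect_error(edgeTableSpec(weight = NULL, effect = NULL),
               class = "tfinfluence_usage_error")
})

test_that("comment lines are skipped", {
  path <- writeTempTable(c("# provenance note", "source\ttarget\tweight",
                           "A\tB\t2.5", "# mid-file comment", "B\tC\t-1"))
  expect_identical(nrow(readEdgeTable(path)), 2L)
})

test_that("edge-TSV round trip is the identity, rows sorted by (source, target)", {
  recs <- randomConnectedRecords(30, extra = 40, seed = 5)
  net <- regulatoryNetwork(edges = recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, path, "tsv")
  back <- readNetwork(path, "tsv")
  expect_same_network(back, net)
  ## a second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(back, path2, "tsv")
  expect_identical(readLines(path2), readLines(path))

  ## empty network: header only
  pathE <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(regulatoryNetwork(), pathE, "tsv")
  expect_identical(readLines(pathE), "source\ttarget\tweight")

  ## toy network: data rows in lexicographic order
  toy <- makeNet(c("b", "a", "a"), c("x", "y", "x"), weight = c(1, 2, 3))
  pathT <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(toy, pathT, "tsv")
  expect_identical(readLines(pathT)[-1],
                   c("a\tx\t3", "a\ty\t2", "b\tx\t1"))
})

test_that("SIF and GraphML exports round-trip structure (and weights, for GraphML)", {
  net <- makeNet(c("A", "A", "B"), c("B", "C", "C"), weight = c(2.5, -1, 0.25))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeNetwork(net, sif, "sif")
  expect_identical(readLines(sif),
                   c("A\treg\tB", "A\treg\tC", "B\treg\tC"))
  backSif <- readNetwork(sif, "sif")
  expect_identical(geneIds(backSif), geneIds(net))
  expect_true(all(edgeTable(backSif)$weight == 1))  # SIF carries no weights

  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, gml, "graphml")
  back <- readNetwork(gml, "graphml")
  expect_same_network(back, net)

  expect_error(writeNetwork(net, sif, "dot"),
               class = "tfinfluence_usage_error")
})

test_that("GraphML stores node annotations as attributes", {
  nd <- data.frame(gene = c("A", "B", "C"),
                   avg_transcript_count = c(1628.215, 316.215, 0.02))
  net <- regulatoryNetwork(
    edges = data.frame(source = "A", target = c("B", "C"), weight = 1),
    nodeData = nd)
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, gml, "graphml")
  back <- readNetwork(gml, "graphml")
  ann <- nodeAnnotations(back)
  expect_equal(ann$avg_transcript_count[match(nd$gene, ann$gene)],
               nd$avg_transcript_count)
})

test_that("crawling a weakly connected provider from any seed equals bulk loading", {
  for (seed in 1:10) {
    recs <- randomConnectedRecords(60, extra = 30, dupRate = 0.4, seed = seed)
    bulk <- regulatoryNetwork(edges = recs)
    provider <- asProvider(recs)
    start <- withr::with_seed(seed, sample(geneIds(bulk), 1))
    crawled <- crawl(provider, start)
    expect_same_network(crawled, bulk)
  }
})

test_that("a crawl explores each discovered gene with at most two queries", {
  recs <- randomConnectedRecords(80, extra = 40, seed = 2)
  provider <- asProvider(recs)
  crawled <- crawl(provider, recs$source[1])
  expect_lte(providerCalls(provider), 2L * numNodes(crawled))
})

test_that("a crawl recovers exactly the seed's weakly connected component", {
  comp1 <- data.frame(source = c("A", "B"), target = c("B", "C"), weight = 1)
  comp2 <- data.frame(source = "X", target = "Y", weight = -2)
  provider <- asProvider(rbind(comp1, comp2))
  net1 <- crawl(provider, "B")
  expect_identical(geneIds(net1), c("A", "B", "C"))
  expect_identical(numEdges(net1), 2L)
  net2 <- crawl(provider, "Y")
  expect_identical(geneIds(net2), c("X", "Y"))
})

test_that("crawlAll unions components; repeated or empty seed lists behave as documented", {
  comp1 <- data.frame(source = c("A", "B"), target = c("B", "C"), weight = 1)
  comp2 <- data.frame(source = "X", target = "Y", weight = -2)
  recs <- rbind(comp1, comp2)
  provider <- asProvider(recs)
  full <- crawlAll(provider, c("A", "X"))
  expect_same_network(full, regulatoryNetwork(edges = recs))

  expect_same_network(crawlAll(provider, c("A", "A", "A")),
                      crawl(provider, "A"))
  expect_identical(numNodes(crawlAll(provider, character(0))), 0L)
})

test_that("a seed with no interactions yields a single-node, zero-edge network", {
  provider <- asProvider(data.frame(source = "A", target = "B", weight = 1))
  net <- crawl(provider, "LONER")
  expect_identical(geneIds(net), "LONER")
  expect_identical(numEdges(net), 0L)
})

test_that("a failing provider raises a crawl error carrying the partial network", {
  ## backend serving A -> B and A -> C; querying B explodes
  flaky <- edgeProvider(
    regulators = function(gene) NULL,
    targets = function(gene) {
      if (gene == "B") stop("backend down")
      if (gene == "A") data.frame(symbol = c("B", "C"), weight = c(1, 2))
      else NULL
    })
  err <- tryCatch(crawl(flaky, "A"), error = function(e) e)
  expect_s3_class(err, "tfinfluence_crawl_error")
  expect_identical(err$symbol, "B")
  expect_s4_class(err$partial, "RegulatoryNetwork")
  expect_identical(numEdges(err$partial), 2L)  # A's answers arrived first
})
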