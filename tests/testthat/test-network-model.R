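test_that("duplicate promoter records collapse to the maximum weight in any order", {
  weights <- c(4.857, 0.834, 0.845)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    net <- regulatoryNetwork()
    for (w in weights[p]) net <- addInteraction(net, "SOX2", "SRF", w)
    expect_identical(numEdges(net), 1L)
    expect_identical(edgeWeight(net, "SOX2", "SRF"), 4.857)
  }
})

test_that("a single record creates both endpoints and one edge", {
  net <- addInteraction(regulatoryNetwork(), "A", "B", 0.5)
  expect_identical(geneIds(net), c("A", "B"))
  expect_identical(numEdges(net), 1L)
  expect_identical(edgeWeight(net, "A", "B"), 0.5)
})

test_that("the default max rule is the signed maximum; abs-max is opt-in", {
  net <- regulatoryNetwork()
  net <- addInteraction(net, "A", "B", -3.0)
  net <- addInteraction(net, "A", "B", 2.0)
  expect_identical(edgeWeight(net, "A", "B"), 2.0)

  netAbs <- regulatoryNetwork(aggregation = "abs-max")
  netAbs <- addInteraction(netAbs, "A", "B", -3.0)
  netAbs <- addInteraction(netAbs, "A", "B", 2.0)
  expect_identical(edgeWeight(netAbs, "A", "B"), -3.0)
  expect_identical(aggregationRule(netAbs), "abs-max")
})

test_that("aggregation is order-independent and idempotent on random multisets", {
  withr::with_seed(42, {
    for (case in 1:20) {
      recs <- data.frame(
        source = sample(c("A", "B", "C"), 12, replace = TRUE),
        target = sample(c("B", "C", "D"), 12, replace = TRUE),
        weight = round(runif(12, -10, 12), 3))
      ref <- addInteractions(regulatoryNetwork(), recs)
      shuffled <- recs[sample(nrow(recs)), ]
      expect_same_network(addInteractions(regulatoryNetwork(), shuffled), ref)
      ## one-at-a-time submission agrees with the bulk path
      oneByOne <- regulatoryNetwork()
      for (i in seq_len(nrow(shuffled)))
        oneByOne <- addInteraction(oneByOne, shuffled$source[i],
                                   shuffled$target[i], shuffled$weight[i])
      expect_same_network(oneByOne, ref)
      ## re-submitting every stored edge changes nothing
      expect_same_network(addInteractions(ref, edgeTable(ref)), ref)
    }
  })
})

test_that("invalid interaction records are rejected", {
  net <- regulatoryNetwork()
  expect_error(addInteraction(net, "A", "B", NaN), class = "tfinfluence_data_error")
  expect_error(addInteraction(net, "A", "B", Inf), class = "tfinfluence_data_error")
  expect_error(addInteraction(net, "", "B", 1), class = "tfinfluence_data_error")
  expect_error(addInteraction(net, "A", "  ", 1), class = "tfinfluence_data_error")
})

test_that("degrees count distinct neighbours, with self-loops counting once each way", {
  net <- makeNet(c("A", "A", "B"), c("B", "C", "C"))
  d <- degrees(net)
  expect_identical(d$gene, c("A", "B", "C"))
  expect_identical(d$in_degree, c(0L, 1L, 2L))
  expect_identical(d$out_degree, c(2L, 1L, 0L))

  expect_identical(nrow(degrees(regulatoryNetwork())), 0L)

  dl <- degrees(makeNet("A", "A"))
  expect_identical(dl$in_degree, 1L)
  expect_identical(dl$out_degree, 1L)
})

test_that("degree sums equal the edge count and match igraph on random networks", {
  for (seed in 1:5) {
    recs <- randomConnectedRecords(40, extra = 60, seed = seed)
    net <- regulatoryNetwork(edges = recs)
    d <- degrees(net)
    expect_identical(sum(d$in_degree), numEdges(net))
    expect_identical(sum(d$out_degree), numEdges(net))
    g <- igraph::graph_from_data_frame(edgeTable(net), directed = TRUE,
                                       vertices = geneIds(net))
    expect_identical(d$in_degree,
      as.integer(igraph::degree(g, v = d$gene, mode = "in", loops = TRUE)))
    expect_identical(d$out_degree,
      as.integer(igraph::degree(g, v = d$gene, mode = "out", loops = TRUE)))
  }
})

test_that("tfSubnetwork keeps exactly the positive-out-degree genes of the parent", {
  net <- makeNet(c("A", "A", "B", "D"), c("B", "C", "C", "E"))
  sub <- tfSubnetwork(net)
  expect_identical(geneIds(sub), c("A", "B", "D"))
  e <- edgeTable(sub)
  expect_identical(paste(e$source, e$target), "A B")
  ## the parent is unmodified
  expect_identical(numNodes(net), 5L)

  ## every node regulating something: identity
  cyc <- makeNet(c("A", "B", "C"), c("B", "C", "A"))
  expect_same_network(tfSubnetwork(cyc), cyc)

  ## star: only the hub survives, with no induced edges
  star <- makeNet("TF", paste0("g", 1:5))
  sub <- tfSubnetwork(star)
  expect_identical(geneIds(sub), "TF")
  expect_identical(numEdges(sub), 0L)
})

test_that("tfSubnetwork membership is characterised by parent out-degree on random networks", {
  for (seed in 1:10) {
    recs <- randomConnectedRecords(50, extra = 40, seed = seed)
    net <- regulatoryNetwork(edges = recs)
    d <- degrees(net)
    sub <- tfSubnetwork(net)
    expect_identical(geneIds(sub), sort(d$gene[d$out_degree > 0L]))
    ## a second pass may shrink further (TFs whose targets were all
    ## effectors), but never grow
    sub2 <- tfSubnetwork(sub)
    expect_true(all(geneIds(sub2) %in% geneIds(sub)))
  }
})

test_that("targetSubnetwork induces sources plus their targets, edges leaving sources only", {
  net <- makeNet(c("A", "B"), c("B", "C"))
  sub <- targetSubnetwork(net, "A")
  expect_identical(geneIds(sub), c("A", "B"))
  expect_identical(paste(edgeTable(sub)$source, edgeTable(sub)$target), "A B")

  expect_identical(numNodes(targetSubnetwork(net, character(0))), 0L)
  expect_error(targetSubnetwork(net, "NOPE"),
               class = "tfinfluence_lookup_error")
  expect_match(tryCatch(targetSubnetwork(net, "NOPE"),
                        error = conditionMessage), "NOPE")
})

test_that("targetSubnetwork over all TFs carries each of their outgoing edges exactly once", {
  recs <- randomConnectedRecords(40, extra = 50, seed = 3)
  net <- regulatoryNetwork(edges = recs)
  d <- degrees(net)
  tfs <- d$gene[d$out_degree > 0L]
  sub <- targetSubnetwork(net, tfs)
  expect_identical(numEdges(sub), sum(d$out_degree))
  expect_identical(numEdges(sub), numEdges(net))
})

test_that("networkSummary tallies nodes, TFs and edge signs", {
  net <- makeNet(c("A", "A", "B"), c("B", "C", "C"), weight = c(2, -1, 0))
  s <- networkSummary(net)
  expect_identical(s$n_genes, 3L)
  expect_identical(s$n_edges, 3L)
  expect_identical(s$n_tf, 2L)
  expect_identical(s$n_effector, 1L)
  expect_identical(c(s$n_positive, s$n_negative, s$n_neutral), c(1L, 1L, 1L))
})
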