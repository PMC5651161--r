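## Fixtures built in code: small deterministic networks and random
## weakly-connected interaction record sets.

makeNet <- function(source, target, weight = 1, ...) {
  regulatoryNetwork(edges = data.frame(source = source, target = target,
                                       weight = weight,
                                       stringsAsFactors = FALSE), ...)
}

## Random weakly connected record set over n genes: a random spanning tree
## with randomly oriented edges, plus `extra` additional random edges and
## optional duplicate promoter-level records (never exceeding the primary).
randomConnectedRecords <- function(n, extra = n, dupRate = 0.3, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n))
    src <- tgt <- character(0)
    if (n > 1) {
      parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)
      flip <- runif(n - 1) < 0.5
      src <- ifelse(flip, genes[2:n], genes[parent])
      tgt <- ifelse(flip, genes[parent], genes[2:n])
    }
    if (extra > 0 && n > 1) {
      src <- c(src, sample(genes, extra, replace = TRUE))
      tgt <- c(tgt, sample(genes, extra, replace = TRUE))
    }
    w <- signif(runif(length(src), -10, 12), 9)
    recs <- data.frame(source = src, target = tgt, weight = w,
                       stringsAsFactors = FALSE)
    dup <- recs[runif(nrow(recs)) < dupRate, , drop = FALSE]
    if (nrow(dup)) {
      dup$weight <- signif(dup$weight - runif(nrow(dup), 0, 1), 9)
      dup$weight <- pmax(dup$weight, -10)
      recs <- rbind(recs, dup)
    }
    recs
  })
}

expect_same_network <- function(a, b) {
  expect_identical(geneIds(a), geneIds(b))
  expect_equal(edgeTable(a), edgeTable(b))
}

tableOneDegrees <- data.frame(
  gene = c("NRF1", "SPIB", "TFAP2A", "MYOD1", "TFAP2B", "ARNT2", "SNAI2",
           "MYOG", "MYF5", "MYF6"),
  in_degree = 0L,
  out_degree = c(2175L, 1778L, 1721L, 1713L, 1652L, 1627L, 1543L, 1435L,
                 1435L, 1435L),
  ri = c(0.99999954, 0.999999438, 0.999999419, 0.999999416, 0.999999395,
         0.999999385, 0.999999352, 0.999999303, 0.999999303, 0.999999303),
  stringsAsFactors = FALSE)

tableThreeDegrees <- data.frame(
  gene = c("Ihf", "H-ns", "NsrR", "Flhdc", "Narp",
           "Uvry", "Gadx", "Dpia", "Glcc", "Gutm"),
  in_degree = c(0L, 0L, 0L, 0L, 0L, 1L, 15L, 6L, 4L, 4L),
  out_degree = c(249L, 186L, 83L, 80L, 65L, 2L, 29L, 11L, 7L, 7L),
  ri = c(0.999999598, 0.999999462, 0.999998795, 0.99999875, 0.999998462,
         0.166641668, 0.141847865, 0.101600146, 0.064928943, 0.064928943),
  stringsAsFactors = FALSE)

tableTwoDegrees <- data.frame(
  gene = c("RUNX1", "ARID5B", "TFAP4", "POU6F1", "ZIC2", "GTF2A1", "POU3F1",
           "SMAD6", "ADNP"),
  in_degree = c(155L, 114L, 190L, 87L, 135L, 100L, 80L, 175L, 132L),
  out_degree = c(556L, 392L, 632L, 268L, 407L, 253L, 198L, 408L, 292L),
  ri = c(0.517749925, 0.49206167, 0.483369442, 0.442040072, 0.438502347,
         0.357562642, 0.331108025, 0.289214257, 0.256880007),
  stringsAsFactors = FALSE)
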