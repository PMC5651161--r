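#' Configuration for the hierarchical signed-network generator
#'
#' The generator emulates the statistical structure of curated
#' transcriptional regulatory networks: a three-tier hierarchy of a few
#' unregulated master TFs, a layer of regulated TFs, and a majority of
#' zero-out-degree effector genes; heavy-tailed out-degrees (a few TFs
#' control most genes); per-TF activator/repressor bias; Z-score-like signed
#' weights inside the dynamic range [-10, 12]; and duplicate promoter-level
#' records for the same gene pair.
#'
#' @param nMaster number of zero-in-degree master TFs.
#' @param nTF number of regulated TFs.
#' @param nEffector number of zero-out-degree effector genes.
#' @param outDegreeExponent tail exponent of the truncated power law the TF
#'   out-degrees are drawn from (P(k) proportional to k^-exponent).
#' @param maxOutDegree out-degree cap; defaults to the number of available
#'   targets (`nTF + nEffector`, self excluded).
#' @param activatorBias length-2 `c(a, b)` of the Beta prior on each TF's
#'   fraction of positive (activating) outgoing edges.
#' @param weightScale scale of the half-normal magnitude distribution of
#'   edge weights (Z-score units), truncated so positive weights stay at or
#'   below 12 and negative ones at or above -10.
#' @param duplicateRate probability that an edge also emits 1-3 extra
#'   promoter-level records. Duplicates carry weights at or below the
#'   primary record's weight, so max-aggregation recovers the primary
#'   exactly; set `mixedSignDuplicates = TRUE` to let them cross zero and
#'   exercise the signed-max rule.
#' @param mixedSignDuplicates allow duplicate records of opposite sign.
#' @param epsilon the regulariser at which the manifest's reference RI values
#'   are computed.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output on every platform (fixed Mersenne-Twister generator kind).
#' @return a `generatorConfig` list, validated.
#' @export
generatorConfig <- function(nMaster = 5, nTF = 60, nEffector = 300,
                            outDegreeExponent = 2.0, maxOutDegree = NULL,
                            activatorBias = c(2, 2), weightScale = 2.0,
                            duplicateRate = 0.25,
                            mixedSignDuplicates = FALSE,
                            epsilon = 1e-3, seed = 1L) {
  counts <- c(nMaster = nMaster, nTF = nTF, nEffector = nEffector)
  if (any(counts < 0) || any(counts != floor(counts)))
    .configError("nMaster, nTF and nEffector must be non-negative integers")
  if (nEffector > 0 && nMaster + nTF < 1)
    .configError("effector genes need at least one TF or master to regulate them")
  if (outDegreeExponent <= 0) .configError("outDegreeExponent must be > 0")
  if (length(activatorBias) != 2L || any(activatorBias <= 0))
    .configError("activatorBias must be c(a, b) with a, b > 0")
  if (weightScale <= 0) .configError("weightScale must be > 0")
  if (duplicateRate < 0 || duplicateRate > 1)
    .configError("duplicateRate must be in [0, 1]")
  if (epsilon <= 0) .configError("epsilon must be > 0")
  structure(list(nMaster = as.integer(nMaster), nTF = as.integer(nTF),
                 nEffector = as.integer(nEffector),
                 outDegreeExponent = outDegreeExponent,
                 maxOutDegree = maxOutDegree,
                 activatorBias = activatorBias, weightScale = weightScale,
                 duplicateRate = duplicateRate,
                 mixedSignDuplicates = mixedSignDuplicates,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "generatorConfig")
}

## Run expr under a private, platform-stable RNG state.
.withGeneratorRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## Half-normal magnitude truncated at cap, by rejection; 9 significant
## digits so the edge-TSV round trip is exact.
.drawMagnitude <- function(n, scale, cap) {
  m <- abs(stats::rnorm(n, 0, scale))
  while (any(bad <- m > cap))
    m[bad] <- abs(stats::rnorm(sum(bad), 0, scale))
  m
}

#' Generate a synthetic hierarchical regulatory network
#'
#' Draws a network under a [generatorConfig()] and returns both the raw
#' interaction record stream (duplicates included, as an edge database would
#' deliver them) and a ground-truth manifest: every gene's tier, its degrees
#' after max-aggregation, its clipped relative influence at the config's
#' epsilon, and its sign-mode polarity score. The manifest is what the
#' analysis pipeline must reproduce when fed the records.
#'
#' @param config a [generatorConfig()].
#' @return list with elements `records` (data.frame `source`, `target`,
#'   `weight`, `promoter`), `manifest` (data.frame `gene`, `tier`,
#'   `in_degree`, `out_degree`, `ri_true`, `polarity_true`) and `config`.
#' @examples
#' sim <- simulateNetwork(generatorConfig(nMaster = 2, nTF = 5,
#'                                        nEffector = 20, seed = 7))
#' head(sim$manifest)
#' @export
simulateNetwork <- function(config = generatorConfig()) {
  if (!inherits(config, "generatorConfig"))
    .configError("config must be a generatorConfig()")
  cfg <- config
  masters <- if (cfg$nMaster) sprintf("M%03d", seq_len(cfg$nMaster)) else character(0)
  tfs <- if (cfg$nTF) sprintf("TF%03d", seq_len(cfg$nTF)) else character(0)
  effectors <- if (cfg$nEffector) sprintf("G%04d", seq_len(cfg$nEffector)) else character(0)
  regulators <- c(masters, tfs)
  targetsPool <- c(tfs, effectors)   # masters receive no incoming edges

  primary <- .withGeneratorRNG(cfg$seed, {
    edges <- vector("list", length(regulators))
    a <- cfg$activatorBias[1]; b <- cfg$activatorBias[2]
    for (i in seq_along(regulators)) {
      reg <- regulators[i]
      allowed <- setdiff(targetsPool, reg)
      if (!length(allowed)) next
      kmax <- min(if (is.null(cfg$maxOutDegree)) length(allowed)
                  else cfg$maxOutDegree, length(allowed))
      ks <- seq_len(kmax)
      k <- sample(ks, 1L, prob = ks^(-cfg$outDegreeExponent))
      tgt <- if (length(allowed) == 1L) allowed else sample(allowed, k)
      pAct <- stats::rbeta(1L, a, b)
      sgn <- ifelse(stats::runif(k) < pAct, 1, -1)
      mag <- .drawMagnitude(k, cfg$weightScale,
                            cap = ifelse(sgn > 0, 12, 10))
      edges[[i]] <- data.frame(source = reg, target = tgt,
                               weight = signif(sgn * mag, 9),
                               stringsAsFactors = FALSE)
    }
    prim <- do.call(rbind, c(edges,
      list(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))))
    ## every regulated TF must have at least one regulator
    if (length(tfs)) {
      unreg <- setdiff(tfs, unique(prim$target))
      fix <- vector("list", length(unreg))
      for (j in seq_along(unreg)) {
        cand <- setdiff(regulators, unreg[j])
        ## drop candidates already regulating this TF (none, by construction)
        if (!length(cand)) next
        src <- if (length(cand) == 1L) cand else sample(cand, 1L)
        sgn <- ifelse(stats::runif(1) < a / (a + b), 1, -1)
        mag <- .drawMagnitude(1L, cfg$weightScale, ifelse(sgn > 0, 12, 10))
        fix[[j]] <- data.frame(source = src, target = unreg[j],
                               weight = signif(sgn * mag, 9),
                               stringsAsFactors = FALSE)
      }
      extra <- do.call(rbind, fix)
      if (!is.null(extra)) {
        ## a fix-up edge may duplicate an existing pair; keep the max
        prim <- .aggregateRecords(rbind(prim, extra), "signed-max")
      }
    }
    prim <- .canonicalEdges(prim)
    prim$promoter <- rep("p1", nrow(prim))

    ## promoter-level duplicates, weights <= the primary (signed), so
    ## max-aggregation provably recovers the primary record
    dup <- list()
    if (cfg$duplicateRate > 0 && nrow(prim)) {
      emits <- stats::runif(nrow(prim)) < cfg$duplicateRate
      for (i in which(emits)) {
        nd <- sample(3L, 1L)
        w <- prim$weight[i]
        wd <- if (cfg$mixedSignDuplicates || w <= 0)
          stats::runif(nd, min = -10, max = w)
        else w * stats::runif(nd)
        dup[[length(dup) + 1L]] <-
          data.frame(source = prim$source[i], target = prim$target[i],
                     weight = signif(wd, 9),
                     promoter = sprintf("p%d", 1L + seq_len(nd)),
                     stringsAsFactors = FALSE)
      }
    }
    list(prim = prim, dup = dup)
  })

  records <- do.call(rbind, c(list(primary$prim), primary$dup))
  rownames(records) <- NULL

  genes <- c(masters, tfs, effectors)
  net <- regulatoryNetwork(edges = primary$prim, nodes = genes)
  d <- degrees(net)
  d <- d[match(genes, d$gene), ]
  pol <- .polarityCounts(net)
  polarity <- pol$score_sign[match(genes, pol$gene)]
  polarity[is.na(polarity)] <- 0
  manifest <- data.frame(
    gene = genes,
    tier = rep(c("master", "tf", "effector"),
               c(length(masters), length(tfs), length(effectors))),
    in_degree = d$in_degree,
    out_degree = d$out_degree,
    ri_true = relativeInfluence(d$in_degree, d$out_degree, cfg$epsilon,
                                clip = TRUE),
    polarity_true = polarity,
    stringsAsFactors = FALSE, row.names = NULL)

  list(records = records, manifest = manifest, config = cfg)
}
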