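---
title: "Relative influence and polarity in transcriptional regulatory networks"
author: "tfinfluence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative influence and polarity in transcriptional regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfinfluence)
```

## The model

A transcriptional regulatory network is a directed graph whose nodes are
genes and whose edges are regulatory interactions: an edge from gene *i* to
gene *j* means the product of *i* (a transcription factor, TF) regulates the
transcription of *j*. Each edge carries a real-valued interaction strength
$S_{i,j}$ on a Z-score scale (dynamic range roughly $-10$ to $12$ in curated
databases such as FANTOM4 EdgeExpress); positive values are activation,
negative values repression. Curated databases like RegulonDB instead record
a categorical effect — activation, repression or dual — which this package
materialises to weights $+1$, $-1$ and $0$ on ingestion.

Operationally, a **TF** is any gene with out-degree above zero; a gene with
zero out-degree is an **effector** (regulated but regulating nothing). Such
networks are strongly hierarchical: a handful of TFs with no transcriptional
regulators of their own ("master" regulators) control thousands of targets,
a middle layer of TFs is itself heavily co-regulated, and the large majority
of genes are effectors.

### Duplicate records and max-weight aggregation

Binding-site predictions are promoter-specific, so a database can hold
several records for the same ordered gene pair, one per promoter region.
`RegulatoryNetwork` stores at most one edge per ordered pair: every
submitted record passes through an aggregation rule that keeps the largest
value. The default is the **signed maximum** — "largest value" read
literally, which is also the only reading exercised by curated examples,
where all duplicates share a sign. An absolute-value maximum (keep the
record with the largest magnitude, ties resolved toward the larger signed
weight) is available via `aggregation = "abs-max"` for users who prefer the
strongest interaction regardless of direction; it is not the default
because it can silently convert an activation into a repression.
Aggregation is order-independent and idempotent, which the test suite
asserts over shuffled record streams.

Self-loops are permitted and count once toward each degree. Gene symbols are
compared exactly after whitespace trimming; case is preserved and
significant.

## Relative influence

For gene $n$ with in-degree $inDeg_n$ (distinct regulators) and out-degree
$outDeg_n$ (distinct targets), the relative influence is

$$
RI_n \;=\; \frac{outDeg_n}{inDeg_n + outDeg_n}
  \;-\; \frac{\epsilon + inDeg_n}{\epsilon + outDeg_n},
$$

with $\epsilon$ a small positive regulariser keeping the second term finite
for effectors. The first term is the fraction of a gene's interactions that
point outward; the second penalises being regulated relative to regulating.
An unregulated hub scores $1 - \epsilon/(\epsilon + outDeg)$, strictly below
1 and increasing toward it with the number of targets; a heavily regulated
gene with few targets scores negative. Reported tables clip negative values
to 0, and an isolated gene (both degrees zero, where the first term is
$0/0$) is defined to score 0 — isolation is non-influence. The raw statistic
is strictly increasing in out-degree (for $outDeg \ge 1$) and strictly
decreasing in in-degree, which the suite verifies exhaustively on the
$[0, 200]^2$ degree grid.

**Choosing $\epsilon$.** The default is $10^{-3}$, the value used for the
human (FANTOM4-derived) reference tables this package regression-tests
against. The corresponding *E. coli* (RegulonDB-derived) reference values
are only consistent with $\epsilon = 10^{-4}$; the two conventions differ
in the sixth decimal and beyond for unregulated hubs. Because the constant
is a tie-breaking regulariser rather than a biological parameter,
`relativeInfluence()` and `influenceTable()` expose it as an argument and
the regression suite pins each reference table at its own $\epsilon$.
Rankings are insensitive to the choice within this range; only the printed
digits move.

Influence tables are ranked by clipped RI descending with ties broken by
gene symbol, so output is reproducible across platforms and runs.

## Overall activators and repressors

A TF's polarity is the algebraic sum of its outgoing interactions,
$\sum_j S_{i,j}$. Two modes are supported:

* **sign mode** (default): each positively weighted target counts $+1$,
  each negatively weighted one $-1$, i.e. the score is
  $n_{pos} - n_{neg}$. This matches the worked arithmetic of the curated
  examples (a TF with 965 activated and 687 repressed targets scores
  $965 - 687 = 278$) and is robust to the weight scale.
* **weight mode**: the raw weights are summed. The two modes can disagree —
  one strong activation can outweigh several weak repressions — which is
  why both scores are reported side by side in `polarityTable()` output.

A positive score labels the TF an *overall activator*, a negative one an
*overall repressor*; zero (including a TF whose edges are all dual) is
*neutral*. Dual edges count toward the out-degree but never move either
score. Only outgoing edges enter: polarity describes a TF's action on its
targets, not how it is itself regulated, and in any case the label is
phenotype- and context-dependent biology that a single network snapshot
cannot settle.

## Crawling an edge database

Curated interaction databases are often consulted gene by gene: ask which
genes regulate gene $g$ and which genes $g$ regulates. `crawl()` reproduces
a whole network from such an interface by breadth-first search — a FIFO
queue of genes to explore and a registry of genes already seen; each
dequeued gene is queried exactly once for regulators and once for targets,
and every record found is submitted through the aggregation rule. The
traversal recovers the weakly connected component of the seed; since
databases can hold several components, `crawlAll()` unions crawls from
several seeds. Exploration order within a level follows the provider's
answer order (the bundled in-memory provider sorts answers
lexicographically), but the resulting network is provably order-invariant,
and the suite checks crawl-equals-bulk-load equality on randomly generated
providers of up to 500 genes.

The `EdgeProvider` class is the seam where a live database client could be
attached; the package itself ships only the in-memory mock
(`asProvider()`), which also serves as the test oracle.

## The synthetic generator

`simulateNetwork()` draws networks with the statistical structure the
analysis assumes, so the entire pipeline is testable without any database
download. An instance has three tiers: `nMaster` master TFs (never
targeted), `nTF` regulated TFs, and `nEffector` effectors (never sources).
Design choices, made once:

* **Out-degrees** of masters and TFs are drawn from a truncated power law
  $P(k) \propto k^{-\gamma}$, default $\gamma = 2$, reflecting the observed
  hierarchy in which a few TFs control most genes. The exponent is
  configurable because curated networks are described as heavy-tailed
  without a fitted distribution.
* **Signs**: each TF draws an activator fraction from a Beta($a$, $b$)
  prior (default $a = b = 2$, mean one half) and signs each outgoing edge
  independently — so the population contains both predominantly activating
  and predominantly repressing TFs, as real networks do.
* **Magnitudes** are half-normal with scale 2 (Z-score units), truncated by
  rejection so positive weights stay $\le 12$ and negative ones $\ge -10$,
  matching the stated dynamic range of curated interaction scores. Weights
  are rounded to 9 significant digits at birth so that the plain-text
  edge-table round trip is exactly lossless.
* **Duplicates**: with probability `duplicateRate` an edge emits 1–3 extra
  promoter-level records whose weights never exceed the primary record's,
  so the ground truth provably survives max-aggregation. Mixed-sign
  duplicates (exercising the signed-max rule across zero) are available
  behind `mixedSignDuplicates = TRUE` but off by default, since curated
  duplicate examples are same-signed.
* **Feasibility**: every regulated TF is guaranteed at least one regulator
  among the masters and other TFs (a fix-up edge is added where the random
  draw left one unregulated).

The default instance — 5 masters, 60 TFs, 300 effectors, duplicate rate
0.25 — is a desk-scale miniature of a curated mammalian network: the same
few-masters / regulated-middle / effector-majority shape at roughly 1/25
the gene count. Validation runs in the suite use instances between ~60 and
~500 genes and 20–50 seeds per property, sizes chosen so the full suite
completes in well under a minute while still exercising heavy-tailed
degrees.

The generator is seeded with a fixed Mersenne–Twister configuration and
restores the caller's RNG state, so identical configurations regenerate
byte-identical record streams and manifests across platforms.

**What the generator does not emulate.** Degrees and signs are independent
across TFs; there is no co-regulation structure (no enrichment of feedback
or feed-forward motifs), no correlation between a TF's in- and out-degree,
no expression dynamics, and gene symbols are synthetic. Passing tests
therefore demonstrate the correctness of the graph machinery and statistics
on hierarchically structured inputs — not that biological conclusions drawn
from any particular curated snapshot are right.

## Numerical and formatting conventions

* Influence and polarity tables are written as TSV with real values printed
  to 9 significant digits, matching the precision of the curated reference
  tables; internal computation is double precision throughout.
* Test tolerances: reference influence values are checked at their printed
  precision (8 or 9 decimals); the one worked example known to be printed
  with different rounding is checked at $10^{-5}$ absolute; everything else
  uses `expect_equal`'s defaults or exact integer identity.
* Ranking ties (equal RI or polarity score) break lexicographically by gene
  symbol.
* The TF subnetwork is a **single pass**: membership is decided by
  out-degree in the full network. A second application can shrink the
  network further (a TF whose only targets were effectors has out-degree 0
  in the subnetwork); that is a documented property, not an invariant.
* One set of curated bottom-of-table reference values is *not* reproducible
  from its printed degree pairs under either $\epsilon$ convention; the
  suite asserts the mismatch so the discrepancy is recorded rather than
  silently absorbed, and those values are never used as references.

## Limitations

* Degrees are unweighted counts; no other centrality (betweenness,
  eigenvector) is computed — the relative-influence statistic is the point.
* The SIF format carries no weights; reading a SIF assigns weight 1.
* No live database clients, layout or visualisation are included.

## A worked run

```{r example}
cfg <- generatorConfig(nMaster = 3, nTF = 12, nEffector = 40, seed = 42)
sim <- simulateNetwork(cfg)
net <- regulatoryNetwork(edges = sim$records, nodes = sim$manifest$gene)
net

head(influenceTable(net), 4)
head(polarityTable(net), 3)
numNodes(tfSubnetwork(net))
```
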