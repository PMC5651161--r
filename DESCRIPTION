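Package: tfinfluence
Title: Relative Influence and Polarity Analysis of Transcriptional
    Regulatory Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing directed, signed, weighted
    transcription-factor regulatory networks. Networks are assembled from
    edge tables or crawled breadth-first from an abstract edge-database
    provider, with promoter-level duplicate records collapsed by a
    max-weight rule. For every gene the package computes the relative
    influence statistic balancing targets against regulators, classifies
    transcription factors as overall activators or repressors via the
    algebraic sum of their outgoing interactions, and extracts the
    TF-only subnetwork. A seeded generator of hierarchical scale-free
    signed networks makes every stage testable without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Transcription,
    GeneRegulation, Software
RoxygenNote: 7.3.3
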