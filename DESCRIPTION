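Package: cosplicex
Title: Gene Cosplicing Network Inference from Exon-Level RNA-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers weighted gene networks that capture coordinated
    alternative splicing (cosplicing) in addition to classical coexpression.
    Each gene is represented as a vector of exon-level read counts per
    sample; per-gene sample-by-sample distance matrices (Canberra or cosine)
    are correlated across all gene pairs with the Mantel procedure, and the
    resulting correlation matrices are soft-thresholded into weighted
    networks. Includes upper-quartile normalization and count filtering,
    scale-free topology statistics, topological-overlap module detection,
    permutation-based module quality and cross-network preservation Z
    statistics, network-specific hub selection and gene-set enrichment,
    edge-factor shift tests (protein-protein interactions, shared
    transcription-factor / splicing-factor / microRNA binding sites,
    chromosomal folding domains, spatial colocalization), and a synthetic
    exon-count generator with planted coexpression and cosplicing modules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    edgeR,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Network, AlternativeSplicing, RNASeq, GeneExpression,
    NetworkInference, Clustering
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'counts-io.R'
    'distance.R'
    'network.R'
    'modules.R'
    'hubs.R'
    'edge-factors.R'
    'simulate.R'
    'pipeline.R'
    'cosplicex-package.R'
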