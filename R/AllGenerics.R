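#' Gene identifiers of an object
#'
#' Returns the gene identifiers carried by a cosplicex object, in their
#' stored order. For [ExonCounts] objects these are the unique gene ids in
#' order of first appearance among the exon rows.
#'
#' @param x An object with gene identifiers.
#' @return Character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Exon identifiers of an object
#'
#' @param x An object with per-exon rows.
#' @return Character vector of exon ids (parallel to the rows of `x`).
#' @export
setGeneric("exonIds", function(x) standardGeneric("exonIds"))

#' Sample identifiers of an object
#'
#' @param x An object with an ordered set of samples.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Network adjacency matrix
#'
#' @param x A [GeneNetwork].
#' @return Symmetric gene-by-gene adjacency matrix in `[0, 1]` with unit
#'   diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Network correlation matrix
#'
#' @param x A [GeneNetwork].
#' @return Symmetric gene-by-gene correlation matrix in `[-1, 1]` with unit
#'   diagonal (the pre-soft-threshold edge weights).
#' @export
setGeneric("netCorrelation", function(x) standardGeneric("netCorrelation"))

#' Soft-thresholding power of a network
#'
#' @param x A [GeneNetwork].
#' @return The power `beta` with `adjacency = |correlation|^beta`.
#' @export
setGeneric("netBeta", function(x) standardGeneric("netBeta"))

#' Network flavor
#'
#' @param x A [GeneNetwork].
#' @return One of `"coexpression"`, `"cosplicing"`, `"cosplicex"`.
#' @export
setGeneric("netFlavor", function(x) standardGeneric("netFlavor"))

#' Whole-network connectivity
#'
#' Connectivity of gene *i* is the sum of its adjacency to all other genes
#' (the unit self-adjacency on the diagonal is excluded).
#'
#' @param x A [GeneNetwork].
#' @return Named numeric vector `k` of per-gene connectivities.
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' Distance matrix of one gene
#'
#' @param x A [GeneDistanceSet].
#' @param gene Gene id (character) or index.
#' @return The symmetric sample-by-sample distance matrix of that gene.
#' @export
setGeneric("distanceMatrix", function(x, gene) standardGeneric("distanceMatrix"))

#' Distance metric of a distance set
#'
#' @param x A [GeneDistanceSet].
#' @return `"canberra"` or `"cosine"`.
#' @export
setGeneric("distanceMetric", function(x) standardGeneric("distanceMetric"))
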