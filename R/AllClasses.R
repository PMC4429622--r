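#' ExonCounts: exon-level RNA-seq counts
#'
#' Container for a genes x exons x samples table of non-negative read
#' counts, stored as a [SummarizedExperiment::SummarizedExperiment] whose
#' rows are exons. `rowData` carries `gene_id` and `exon_id`; `exon_id` is
#' unique within each gene and exon order within a gene is preserved.
#'
#' @slot .Data inherits all SummarizedExperiment slots; the single assay is
#'   named `"counts"`.
#'
#' @param counts Numeric matrix of non-negative counts, exons in rows,
#'   samples in columns. Column names are the sample ids.
#' @param geneId Character vector, one gene id per exon row.
#' @param exonId Character vector, one exon id per row, unique within gene.
#'
#' @return An `ExonCounts` object.
#' @examples
#' m <- matrix(c(5, 2, 0, 7, 1, 3), nrow = 3,
#'             dimnames = list(NULL, c("s1", "s2")))
#' ec <- ExonCounts(m, geneId = c("g1", "g1", "g2"),
#'                  exonId = c("e1", "e2", "e1"))
#' geneIds(ec)
#' @aliases ExonCounts-class
#' @export ExonCounts
#' @exportClass ExonCounts
.ExonCounts <- setClass("ExonCounts",
    contains = "SummarizedExperiment")

setValidity("ExonCounts", function(object) {
    msg <- NULL
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("gene_id", "exon_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'gene_id' and 'exon_id'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cts))
            msg <- c(msg, "counts must not contain NA")
        else if (any(cts < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(msg) && all(c("gene_id", "exon_id") %in% colnames(rd))) {
        key <- paste(rd$gene_id, rd$exon_id, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "exon_id must be unique within each gene")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname ExonCounts-class
ExonCounts <- function(counts, geneId, exonId) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    stopifnot(length(geneId) == nrow(counts),
              length(exonId) == nrow(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = as.character(geneId),
                                       exon_id = as.character(exonId)))
    .ExonCounts(se)
}

#' GeneDistanceSet: per-gene sample distance matrices
#'
#' For each gene, the symmetric N x N matrix of distances between all sample
#' pairs of its exon-count vector, under the Canberra or cosine metric. The
#' sample order is identical across genes.
#'
#' @slot metric `"canberra"` or `"cosine"`.
#' @slot geneIds Character vector of gene ids.
#' @slot sampleIds Character vector of sample ids (length N).
#' @slot distances 3-d array `[N, N, n_genes]` of distances; each slice is
#'   symmetric with a zero diagonal.
#'
#' @aliases GeneDistanceSet-class
#' @exportClass GeneDistanceSet
.GeneDistanceSet <- setClass("GeneDistanceSet",
    slots = c(metric = "character",
              geneIds = "character",
              sampleIds = "character",
              distances = "array"))

setValidity("GeneDistanceSet", function(object) {
    msg <- NULL
    if (!object@metric %in% c("canberra", "cosine"))
        msg <- c(msg, "metric must be 'canberra' or 'cosine'")
    d <- dim(object@distances)
    n <- length(object@sampleIds)
    if (length(d) != 3L || d[1L] != n || d[2L] != n ||
        d[3L] != length(object@geneIds))
        msg <- c(msg, "distances must be an [N, N, n_genes] array")
    else if (any(object@distances < -1e-12))
        msg <- c(msg, "distances must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' GeneNetwork: a weighted gene network
#'
#' A symmetric gene x gene correlation matrix and its soft-thresholded
#' adjacency `|r|^beta`. Flavors: `"coexpression"` (Pearson correlation of
#' exon-summed gene totals), `"cosplicing"` (Mantel correlation of cosine
#' distance matrices), `"cosplicex"` (Mantel correlation of Canberra
#' distance matrices).
#'
#' @slot flavor One of `"coexpression"`, `"cosplicing"`, `"cosplicex"`.
#' @slot beta Positive soft-thresholding power.
#' @slot geneIds Character vector of gene ids (row/col order).
#' @slot correlation Symmetric matrix in `[-1, 1]`, unit diagonal.
#' @slot adjacency Symmetric matrix `|correlation|^beta`, unit diagonal.
#'
#' @aliases GeneNetwork-class
#' @exportClass GeneNetwork
.GeneNetwork <- setClass("GeneNetwork",
    slots = c(flavor = "character",
              beta = "numeric",
              geneIds = "character",
              correlation = "matrix",
              adjacency = "matrix"))

setValidity("GeneNetwork", function(object) {
    msg <- NULL
    n <- length(object@geneIds)
    r <- object@correlation
    a <- object@adjacency
    if (!object@flavor %in% c("coexpression", "cosplicing", "cosplicex"))
        msg <- c(msg, "unknown flavor")
    if (length(object@beta) != 1L || object@beta <= 0)
        msg <- c(msg, "beta must be a single positive number")
    if (!all(dim(r) == c(n, n)) || !all(dim(a) == c(n, n)))
        msg <- c(msg, "matrices must be n_genes x n_genes")
    else {
        if (max(abs(r - t(r))) > 1e-10 || max(abs(a - t(a))) > 1e-10)
            msg <- c(msg, "correlation and adjacency must be symmetric")
        if (any(abs(r) > 1 + 1e-10))
            msg <- c(msg, "correlation must lie in [-1, 1]")
        if (max(abs(a - abs(r)^object@beta)) > 1e-12)
            msg <- c(msg, "adjacency must equal |correlation|^beta")
        if (max(abs(diag(a) - 1)) > 1e-12)
            msg <- c(msg, "adjacency diagonal must be 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' AnnotationBundle: external per-gene and per-pair features
#'
#' Holds the optional annotation tables used by the edge-factor analyses:
#' known protein-protein interaction (PPI) pairs, per-gene transcription
#' factor binding site (TFBS) sets, per-gene splicing factor binding site
#' (SFBS) multiplicity vectors of length 21 (one entry per splicing factor,
#' in a fixed documented order), per-gene microRNA site sets, chromosomal
#' folding-domain intervals and spatial colocalization lists. Any component
#' may be absent (empty).
#'
#' @slot ppi Two-column character matrix of unordered gene pairs.
#' @slot tfbs Named list: gene id -> character vector of factor ids.
#' @slot sfbs Numeric matrix, genes in rows, 21 columns of non-negative
#'   multiplicities.
#' @slot mirna Named list: gene id -> character vector of site ids.
#' @slot domains data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `domain_id` (0-based half-open intervals).
#' @slot colocal Named list: gene id -> character vector of colocalized
#'   gene ids.
#'
#' @param ppi,tfbs,sfbs,mirna,domains,colocal See slots; all optional.
#' @return An `AnnotationBundle`.
#' @aliases AnnotationBundle-class
#' @export AnnotationBundle
#' @exportClass AnnotationBundle
.AnnotationBundle <- setClass("AnnotationBundle",
    slots = c(ppi = "matrix", tfbs = "list", sfbs = "matrix",
              mirna = "list", domains = "data.frame", colocal = "list"))

setValidity("AnnotationBundle", function(object) {
    msg <- NULL
    if (length(object@ppi) && ncol(object@ppi) != 2L)
        msg <- c(msg, "ppi must have two columns")
    if (length(object@sfbs)) {
        if (ncol(object@sfbs) != 21L)
            msg <- c(msg, "sfbs vectors must have length 21")
        else if (any(object@sfbs < 0))
            msg <- c(msg, "sfbs multiplicities must be non-negative")
    }
    if (nrow(object@domains)) {
        need <- c("gene_id", "chrom", "start", "end", "domain_id")
        if (!all(need %in% colnames(object@domains)))
            msg <- c(msg, paste("domains needs columns:",
                                paste(need, collapse = ", ")))
        else if (any(object@domains$start < 0) ||
                 any(object@domains$start >= object@domains$end))
            msg <- c(msg, "domain intervals must satisfy 0 <= start < end")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname AnnotationBundle-class
AnnotationBundle <- function(ppi = NULL, tfbs = NULL, sfbs = NULL,
                             mirna = NULL, domains = NULL, colocal = NULL) {
    if (is.null(ppi))
        ppi <- matrix(character(0), ncol = 2)
    ppi <- as.matrix(ppi)
    storage.mode(ppi) <- "character"
    if (is.null(sfbs))
        sfbs <- matrix(numeric(0), ncol = 21)
    sfbs <- as.matrix(sfbs)
    if (is.null(domains))
        domains <- data.frame(gene_id = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              domain_id = character(0))
    .AnnotationBundle(ppi = ppi,
                      tfbs = if (is.null(tfbs)) list() else as.list(tfbs),
                      sfbs = sfbs,
                      mirna = if (is.null(mirna)) list() else as.list(mirna),
                      domains = as.data.frame(domains),
                      colocal = if (is.null(colocal)) list()
                                else as.list(colocal))
}

## ---- accessors ----

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExonCounts", function(x)
    unique(SummarizedExperiment::rowData(x)$gene_id))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneDistanceSet", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneNetwork", function(x) x@geneIds)

#' @rdname exonIds
#' @export
setMethod("exonIds", "ExonCounts", function(x)
    SummarizedExperiment::rowData(x)$exon_id)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ExonCounts", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GeneDistanceSet", function(x) x@sampleIds)

#' Exon-level counts matrix
#'
#' @param object An [ExonCounts].
#' @param ... Ignored.
#' @return The exon x sample counts matrix.
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "ExonCounts", function(object, ...)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "GeneNetwork", function(x) x@adjacency)

#' @rdname netCorrelation
#' @export
setMethod("netCorrelation", "GeneNetwork", function(x) x@correlation)

#' @rdname netBeta
#' @export
setMethod("netBeta", "GeneNetwork", function(x) x@beta)

#' @rdname netFlavor
#' @export
setMethod("netFlavor", "GeneNetwork", function(x) x@flavor)

#' @rdname connectivity
#' @export
setMethod("connectivity", "GeneNetwork", function(x) {
    k <- rowSums(x@adjacency) - diag(x@adjacency)
    names(k) <- x@geneIds
    k
})

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "GeneDistanceSet", function(x, gene) {
    if (is.character(gene)) {
        gene <- match(gene, x@geneIds)
        if (is.na(gene))
            stop("gene not found in GeneDistanceSet")
    }
    m <- x@distances[, , gene]
    dimnames(m) <- list(x@sampleIds, x@sampleIds)
    m
})

#' @rdname distanceMetric
#' @export
setMethod("distanceMetric", "GeneDistanceSet", function(x) x@metric)

#' Number of genes in a GeneDistanceSet
#' @param x A [GeneDistanceSet].
#' @return Integer, the number of genes.
#' @export
setMethod("length", "GeneDistanceSet", function(x) length(x@geneIds))

## ---- show methods ----

setMethod("show", "ExonCounts", function(object) {
    cat("ExonCounts:", length(geneIds(object)), "genes,",
        nrow(object), "exons,", ncol(object), "samples\n")
})

setMethod("show", "GeneDistanceSet", function(object) {
    cat("GeneDistanceSet (", object@metric, "): ",
        length(object@geneIds), " genes, ",
        length(object@sampleIds), " samples\n", sep = "")
})

setMethod("show", "GeneNetwork", function(object) {
    k <- rowSums(object@adjacency) - 1
    cat("GeneNetwork '", object@flavor, "': ",
        length(object@geneIds), " genes, beta = ", object@beta,
        ", mean connectivity = ", signif(mean(k), 4), "\n", sep = "")
})

setMethod("show", "AnnotationBundle", function(object) {
    cat("AnnotationBundle: ",
        nrow(object@ppi), " PPI pairs, ",
        length(object@tfbs), " TFBS sets, ",
        nrow(object@sfbs), " SFBS vectors, ",
        length(object@mirna), " microRNA sets, ",
        nrow(object@domains), " domain rows, ",
        length(object@colocal), " colocalization lists\n", sep = "")
})
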