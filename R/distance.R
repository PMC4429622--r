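#' Canberra distance matrix of one gene
#'
#' For a gene represented as an exon x sample count matrix, computes the
#' symmetric sample x sample Canberra distance matrix
#' \deqn{d(i,j) = \sum_e |a_{ei} - a_{ej}| / (a_{ei} + a_{ej})}
#' where a term with \eqn{a_{ei} = a_{ej} = 0} contributes 0. Each exon
#' contributes a value in `[0, 1]`, so distances lie in `[0, p]` for a gene
#' with `p` exons. The metric is sensitive to both expression-level and
#' exon-inclusion changes.
#'
#' @param geneCounts Non-negative numeric matrix, exons in rows, samples in
#'   columns (at least 2).
#' @return Symmetric N x N matrix with zero diagonal.
#' @examples
#' canberraDistanceMatrix(cbind(i = c(1, 3), j = c(3, 1)))  # 1.0 off-diagonal
#' @export
canberraDistanceMatrix <- function(geneCounts) {
    geneCounts <- as.matrix(geneCounts)
    n <- ncol(geneCounts)
    if (n < 2L)
        stop("need at least 2 samples")
    if (any(geneCounts < 0))
        stop("counts must be non-negative")
    d <- matrix(0, n, n, dimnames = list(colnames(geneCounts),
                                         colnames(geneCounts)))
    for (i in seq_len(n - 1L)) {
        xi <- geneCounts[, i]
        rest <- geneCounts[, (i + 1L):n, drop = FALSE]
        num <- abs(rest - xi)
        den <- rest + xi
        terms <- num / den
        terms[den == 0] <- 0
        v <- colSums(terms)
        d[i, (i + 1L):n] <- v
        d[(i + 1L):n, i] <- v
    }
    d
}

#' Cosine distance matrix of one gene
#'
#' Computes \eqn{d(i,j) = 1 - a_i \cdot a_j / (\|a_i\| \|a_j\|)} between the
#' exon-count vectors of every sample pair. The measure depends only on the
#' direction of the exon vector, i.e. on relative exon inclusion, and is
#' unaffected by changes in overall gene expression level. Conventions for
#' degenerate vectors: both all-zero gives 0, exactly one all-zero gives 1
#' (such genes are normally removed by filtering).
#'
#' @inheritParams canberraDistanceMatrix
#' @return Symmetric N x N matrix with zero diagonal; entries in `[0, 1]`
#'   for non-negative counts.
#' @examples
#' cosineDistanceMatrix(cbind(a = c(1, 0), b = c(0, 1)))  # 1 off-diagonal
#' @export
cosineDistanceMatrix <- function(geneCounts) {
    geneCounts <- as.matrix(geneCounts)
    n <- ncol(geneCounts)
    if (n < 2L)
        stop("need at least 2 samples")
    if (any(geneCounts < 0))
        stop("counts must be non-negative")
    nrm <- sqrt(colSums(geneCounts^2))
    zero <- nrm == 0
    scl <- ifelse(zero, 1, nrm)
    u <- sweep(geneCounts, 2L, scl, `/`)
    d <- 1 - crossprod(u)
    if (any(zero)) {
        d[zero, ] <- 1
        d[, zero] <- 1
        d[zero, zero] <- 0
    }
    d[d < 0] <- 0                # numerical noise on collinear vectors
    diag(d) <- 0
    dimnames(d) <- list(colnames(geneCounts), colnames(geneCounts))
    d
}

#' Per-gene sample distance matrices for all genes
#'
#' Computes one sample x sample distance matrix per gene under the chosen
#' metric, with identical sample order across genes. This is the first step
#' of cosplicing network construction.
#'
#' @param x An [ExonCounts] (normally filtered).
#' @param metric `"canberra"` (CoSplicEx) or `"cosine"` (cosplicing).
#' @return A [GeneDistanceSet].
#' @export
allGeneDistances <- function(x, metric = c("canberra", "cosine")) {
    metric <- match.arg(metric)
    fun <- switch(metric, canberra = canberraDistanceMatrix,
                  cosine = cosineDistanceMatrix)
    gid <- SummarizedExperiment::rowData(x)$gene_id
    genes <- unique(gid)
    n <- ncol(x)
    cts <- counts(x)
    arr <- array(0, dim = c(n, n, length(genes)))
    rows <- split(seq_along(gid), factor(gid, levels = genes))
    for (g in seq_along(genes))
        arr[, , g] <- fun(cts[rows[[g]], , drop = FALSE])
    .GeneDistanceSet(metric = metric, geneIds = genes,
                     sampleIds = colnames(x), distances = arr)
}

#' Export one gene's distance matrix as TSV
#'
#' @param x A [GeneDistanceSet].
#' @param gene Gene id or index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(x, gene, path) {
    m <- distanceMatrix(x, gene)
    utils::write.table(data.frame(sample = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
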