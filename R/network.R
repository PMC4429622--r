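#' Mantel correlation of two distance matrices
#'
#' Pearson correlation over the paired lower-triangle (off-diagonal)
#' entries of two symmetric sample x sample distance matrices. This is the
#' edge statistic of the cosplicing and CoSplicEx networks: two genes are
#' strongly connected when samples that differ in one gene's exon profile
#' also differ in the other's.
#'
#' @param d1,d2 Symmetric N x N matrices over the same samples, N >= 4.
#' @return A number in `[-1, 1]`; 0 (with a warning) when either triangle
#'   has zero variance.
#' @export
mantelCorrelation <- function(d1, d2) {
    d1 <- as.matrix(d1)
    d2 <- as.matrix(d2)
    if (!all(dim(d1) == dim(d2)))
        stop("distance matrices must have identical dimensions")
    if (nrow(d1) < 4L)
        stop("need at least 4 samples for a Mantel correlation")
    x <- .lowerTri(d1)
    y <- .lowerTri(d2)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance in a distance triangle; returning 0")
        return(0)
    }
    stats::cor(x, y)
}

## Gene x triangle matrix of centered, L2-normalized lower triangles; rows
## with zero variance are set to 0 (their Mantel correlations are 0).
.mantelBasis <- function(dset) {
    arr <- dset@distances
    n <- dim(arr)[1L]
    g <- dim(arr)[3L]
    lt <- lower.tri(matrix(0, n, n))
    m <- matrix(0, g, sum(lt))
    for (i in seq_len(g))
        m[i, ] <- arr[, , i][lt]
    m <- m - rowMeans(m)
    nrm <- sqrt(rowSums(m^2))
    flat <- nrm < 1e-300
    if (any(flat))
        warning(sum(flat), " gene(s) with constant distance matrices; ",
                "their Mantel correlations are set to 0")
    m[flat, ] <- 0
    nrm[flat] <- 1
    m / nrm
}

#' Build a weighted gene network
#'
#' Assembles the gene x gene correlation matrix for one network flavor and
#' soft-thresholds it into an adjacency `|r|^beta`:
#' \itemize{
#'   \item `"coexpression"`: Pearson correlation across samples of the
#'     exon-summed gene totals; `input` is an [ExonCounts] or a
#'     genes x samples numeric matrix.
#'   \item `"cosplicing"`: Mantel correlations of cosine [GeneDistanceSet]
#'     matrices.
#'   \item `"cosplicex"`: Mantel correlations of Canberra [GeneDistanceSet]
#'     matrices.
#' }
#' The Mantel flavors use a fast path: each gene's lower distance triangle
#' is centered and L2-normalized, so the full correlation matrix is a single
#' matrix crossproduct; it equals the pairwise [mantelCorrelation()] loop to
#' within 1e-10. For more than `chunk` genes the product is computed in row
#' blocks to bound memory.
#'
#' @param input An [ExonCounts]/matrix (coexpression) or a
#'   [GeneDistanceSet] (Mantel flavors).
#' @param flavor Network flavor; defaults from the input type.
#' @param beta Positive soft-thresholding power (default 6).
#' @param chunk Row-block size for the Mantel crossproduct.
#' @return A [GeneNetwork].
#' @export
buildNetwork <- function(input,
                         flavor = c("coexpression", "cosplicing",
                                    "cosplicex"),
                         beta = 6, chunk = 20000L) {
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
        stop("beta must be a single positive number")
    flavor <- match.arg(flavor)
    if (flavor == "coexpression") {
        tot <- if (is(input, "ExonCounts")) geneTotals(input)
               else as.matrix(input)
        genes <- rownames(tot)
        if (is.null(genes))
            genes <- paste0("gene", seq_len(nrow(tot)))
        r <- suppressWarnings(stats::cor(t(tot)))
        if (anyNA(r)) {
            warning("zero-variance gene totals; their correlations are 0")
            r[is.na(r)] <- 0
        }
    } else {
        if (!is(input, "GeneDistanceSet"))
            stop("flavor '", flavor, "' requires a GeneDistanceSet")
        want <- if (flavor == "cosplicing") "cosine" else "canberra"
        if (distanceMetric(input) != want)
            stop("flavor '", flavor, "' requires metric '", want, "'")
        b <- .mantelBasis(input)
        genes <- geneIds(input)
        g <- nrow(b)
        if (g <= chunk) {
            r <- tcrossprod(b)
        } else {
            r <- matrix(0, g, g)
            for (start in seq(1L, g, by = chunk)) {
                idx <- start:min(start + chunk - 1L, g)
                r[idx, ] <- b[idx, , drop = FALSE] %*% t(b)
            }
        }
    }
    r[r > 1] <- 1
    r[r < -1] <- -1
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(genes, genes)
    a <- abs(r)^beta
    .GeneNetwork(flavor = flavor, beta = beta, geneIds = genes,
                 correlation = r, adjacency = a)
}

#' Scale-free topology fit
#'
#' R-squared of the regression of `log10(frequency)` on `log10(mean k)`
#' over `nBins` equal-width connectivity bins; empty bins and bins with
#' non-positive mean connectivity are dropped. A value near 1 indicates a
#' power-law (scale-free) connectivity distribution.
#'
#' @param k Numeric vector of per-gene connectivities.
#' @param nBins Number of equal-width bins (default 10).
#' @return R-squared in `[0, 1]`; 0 (with a warning) when fewer than two
#'   usable bins remain.
#' @export
scaleFreeFit <- function(k, nBins = 10L) {
    if (all(k <= 0)) {
        warning("all connectivities are zero; scale-free R^2 reported as 0")
        return(0)
    }
    breaks <- seq(min(k), max(k), length.out = nBins + 1L)
    if (breaks[1L] == breaks[nBins + 1L]) {
        warning("constant connectivity; scale-free R^2 reported as 0")
        return(0)
    }
    bin <- cut(k, breaks = breaks, include.lowest = TRUE)
    freq <- as.numeric(table(bin))
    meank <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(meank) & meank > 0
    if (sum(ok) < 2L) {
        warning("fewer than 2 usable connectivity bins; R^2 reported as 0")
        return(0)
    }
    fit <- stats::lm(log10(freq[ok]) ~ log10(as.numeric(meank[ok])))
    suppressWarnings(summary(fit)$r.squared)  # quiet on perfect fits
}

## Topology statistics from a bare adjacency matrix (unit diagonal).
.topologyFromAdjacency <- function(a, nBins = 10L) {
    n <- nrow(a)
    k <- rowSums(a) - diag(a)
    sk <- sum(k)
    density <- sk / (n * (n - 1))
    centralization <- (n / (n - 2)) * (max(k) / (n - 1) - density)
    heterogeneity <- if (sk == 0) 0 else sqrt(n * sum(k^2) / sk^2 - 1)
    r2 <- if (sk == 0) {
        warning("all-zero off-diagonal adjacency")
        0
    } else scaleFreeFit(k, nBins = nBins)
    list(connectivity = k, density = density,
         centralization = centralization, heterogeneity = heterogeneity,
         scale_free_r2 = r2, n_genes = n)
}

#' Network topology statistics
#'
#' Classical weighted-network statistics: per-gene connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}; density
#' \eqn{\sum_i k_i / (n(n-1))}; centralization
#' \eqn{(n/(n-2)) (\max_i k_i/(n-1) - density)}; heterogeneity, the
#' population coefficient of variation of k,
#' \eqn{\sqrt{n \sum k^2 / (\sum k)^2 - 1}}; and the scale-free fit R^2
#' from [scaleFreeFit()].
#'
#' @param net A [GeneNetwork] with at least 3 genes.
#' @param nBins Bins for [scaleFreeFit()].
#' @return List with `connectivity` (named vector), `density`,
#'   `centralization`, `heterogeneity`, `scale_free_r2`, `n_genes`.
#' @export
topologyStats <- function(net, nBins = 10L) {
    if (length(geneIds(net)) < 3L)
        stop("need at least 3 genes")
    st <- .topologyFromAdjacency(adjacency(net), nBins = nBins)
    names(st$connectivity) <- geneIds(net)
    st
}

#' Scale-free convergence over soft-thresholding powers
#'
#' Re-thresholds one correlation matrix at a series of powers and tabulates
#' the scale-free fit and mean connectivity at each, the standard diagnostic
#' for choosing `beta`.
#'
#' @param net A [GeneNetwork] (its correlation matrix is reused).
#' @param betas Increasing vector of non-negative powers (0 gives the
#'   degenerate all-ones adjacency with density 1).
#' @param nBins Bins for [scaleFreeFit()].
#' @return data.frame with columns `beta`, `scale_free_r2`, `mean_k`,
#'   `density`, `centralization`, `heterogeneity`.
#' @export
scaleFreeConvergence <- function(net, betas = c(1, 2, 4, 6, 8, 10),
                                 nBins = 10L) {
    if (any(betas < 0) || is.unsorted(betas))
        stop("betas must be non-negative and sorted")
    rows <- lapply(betas, function(b) {
        a <- abs(net@correlation)^b
        diag(a) <- 1
        st <- suppressWarnings(.topologyFromAdjacency(a, nBins = nBins))
        data.frame(beta = b, scale_free_r2 = st$scale_free_r2,
                   mean_k = mean(st$connectivity), density = st$density,
                   centralization = st$centralization,
                   heterogeneity = st$heterogeneity)
    })
    do.call(rbind, rows)
}

#' Export a network as a gene-pair edge list
#'
#' Writes a TSV with columns `gene_a`, `gene_b`, `r`, `adjacency` for every
#' unordered gene pair with adjacency at or above `threshold`.
#'
#' @param net A [GeneNetwork].
#' @param path Output path.
#' @param threshold Minimum adjacency to include (default 0: all pairs).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path, threshold = 0) {
    g <- geneIds(net)
    idx <- which(lower.tri(net@adjacency), arr.ind = TRUE)
    keep <- net@adjacency[idx] >= threshold
    idx <- idx[keep, , drop = FALSE]
    dt <- data.frame(gene_a = g[idx[, 2L]], gene_b = g[idx[, 1L]],
                     r = net@correlation[idx],
                     adjacency = net@adjacency[idx])
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}
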