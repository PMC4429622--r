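#' Topological overlap matrix (TOM)
#'
#' Smooths an adjacency matrix by shared-neighbor structure:
#' \deqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and \eqn{TOM_{ii}=1}.
#' `1 - TOM` is the dissimilarity used for module detection.
#'
#' @param net A [GeneNetwork] (or a symmetric adjacency matrix in `[0, 1]`).
#' @return Symmetric gene x gene matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @export
topologicalOverlap <- function(net) {
    a <- if (is(net, "GeneNetwork")) adjacency(net) else as.matrix(net)
    diag(a) <- 0
    k <- rowSums(a)
    l <- a %*% a                    # diag(a)=0 already excludes u = i, j
    denom <- outer(k, k, pmin) + 1 - a
    tom <- (l + a) / denom
    diag(tom) <- 1
    tom[tom > 1] <- 1
    tom[tom < 0] <- 0
    dimnames(tom) <- if (is(net, "GeneNetwork"))
        list(geneIds(net), geneIds(net)) else dimnames(a)
    tom
}

#' Detect network modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `minModuleSize` are merged
#' into `"unassigned"` and the remaining modules are labeled `"M1"`,
#' `"M2"`, ... by decreasing size. Deterministic given the input.
#'
#' @param net A [GeneNetwork].
#' @param minModuleSize Smallest cluster kept as a module (default 30).
#' @param cutHeight Tree cut height on the `1 - TOM` scale (default
#'   0.995): with a soft-thresholding power of 6, a coherent module with
#'   within-module correlations around 0.4 merges at heights between 0.99
#'   and 1, while unrelated genes merge essentially at 1.
#' @return Named character vector: gene id -> module label (with
#'   `"unassigned"` reserved).
#' @export
detectModules <- function(net, minModuleSize = 30L, cutHeight = 0.995) {
    genes <- geneIds(net)
    n <- length(genes)
    if (minModuleSize > n) {
        out <- rep("unassigned", n)
        names(out) <- genes
        return(out)
    }
    dis <- 1 - topologicalOverlap(net)
    if (max(dis) - min(dis) < 1e-12)
        message("degenerate (constant) dissimilarity; single cluster")
    hc <- stats::hclust(stats::as.dist(dis), method = "average")
    if (is.unsorted(hc$height))   # guard tiny FP inversions on tied input
        hc$height <- cummax(hc$height)
    raw <- stats::cutree(hc, h = cutHeight)
    sizes <- table(raw)
    keep <- names(sizes)[sizes >= minModuleSize]
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    lab <- rep("unassigned", n)
    for (i in seq_along(ord))
        lab[raw == as.integer(ord[i])] <- paste0("M", i)
    names(lab) <- genes
    lab
}

#' Module sizes
#'
#' @param modules Named character vector from [detectModules()].
#' @return Table of label -> size.
#' @export
moduleSizes <- function(modules) table(modules)

#' Color names for module labels
#'
#' Maps size-ranked module labels to conventional color names for display
#' (`"unassigned"` maps to `"grey"`).
#'
#' @param modules Named character vector of module labels.
#' @return data.frame with `module` and `color`.
#' @export
moduleColorMap <- function(modules) {
    palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                 "black", "pink", "magenta", "purple", "greenyellow",
                 "tan", "salmon", "cyan", "midnightblue", "lightcyan")
    labs <- setdiff(unique(modules), "unassigned")
    labs <- labs[order(as.integer(sub("^M", "", labs)))]
    col <- rep(palette, length.out = length(labs))
    rbind(data.frame(module = labs, color = col),
          data.frame(module = "unassigned", color = "grey"))
}

## Observed module statistics on a network adjacency.
##   density:     mean within-module off-diagonal adjacency
##   separability: density / mean module-to-outside adjacency
##   kim:         within-module connectivity vector
.moduleStats <- function(a, idx) {
    s <- length(idx)
    sub <- a[idx, idx, drop = FALSE]
    within <- (sum(sub) - s) / (s * (s - 1))   # unit diagonal excluded
    rowAll <- rowSums(a[idx, , drop = FALSE]) - 1
    outSum <- sum(rowAll) - (sum(sub) - s)
    nOut <- s * (nrow(a) - s)
    outMean <- if (nOut > 0) outSum / nOut else NA_real_
    sep <- if (is.na(outMean) || outMean <= 0) NA_real_ else within / outMean
    kim <- rowSums(sub) - 1
    list(density = within, separability = sep, kim = kim, kall = rowAll)
}

## Shared permutation machinery: random same-size gene sets drawn (without
## replacement) from the SORTED gene ids, so results are invariant to the
## gene order of the input networks given the same seed.
.nullSets <- function(genes, size, nPerm, seed) {
    sortedGenes <- sort(genes)
    .withSeed(seed, lapply(seq_len(nPerm), function(i)
        sample(sortedGenes, size)))
}

#' Permutation Z statistics of module quality
#'
#' For every module: observed within-module density, separability (within
#' density over module-to-outside mean adjacency) and a connectivity
#' statistic (Pearson correlation between intramodular and whole-network
#' connectivity of the module genes), each converted to a Z score against
#' `nPerm` random gene sets of the same size. `Z_summary` is the mean of
#' `Z_density` and `Z_connectivity` (components whose permutation null is
#' degenerate, e.g. correlations that are identically 1, are undefined and
#' excluded). Z < 2 indicates poor quality; Z > 10
#' high quality.
#'
#' @param net The [GeneNetwork] the modules were detected in.
#' @param modules Named character vector from [detectModules()].
#' @param nPerm Number of permutations (> 0).
#' @param seed Integer seed for the permutation stream (mandatory for
#'   reproducibility).
#' @return data.frame with one row per module: `module`, `size`,
#'   `Z_density`, `Z_connectivity`, `Z_separability`, `Z_summary`,
#'   `n_permutations`. Modules of size < 3 get `NA` statistics.
#' @export
moduleQuality <- function(net, modules, nPerm = 200L, seed) {
    if (missing(seed))
        stop("a seed is required for the permutation null")
    if (nPerm < 1L)
        stop("nPerm must be positive (cannot form a permutation null)")
    a <- adjacency(net)
    genes <- geneIds(net)
    modules <- modules[genes]
    labs <- setdiff(unique(modules), "unassigned")
    rows <- lapply(labs, function(m) {
        idx <- which(modules == m)
        s <- length(idx)
        if (s < 3L) {
            warning("module ", m, " has fewer than 3 genes; reported as NA")
            return(data.frame(module = m, size = s, Z_density = NA_real_,
                              Z_connectivity = NA_real_,
                              Z_separability = NA_real_,
                              Z_summary = NA_real_,
                              n_permutations = nPerm))
        }
        obs <- .moduleStats(a, idx)
        obsConn <- suppressWarnings(stats::cor(obs$kim, obs$kall))
        if (is.na(obsConn)) obsConn <- 0
        sets <- .nullSets(genes, s, nPerm, seed)
        nullMat <- vapply(sets, function(gset) {
            st <- .moduleStats(a, match(gset, genes))
            cc <- suppressWarnings(stats::cor(st$kim, st$kall))
            c(st$density, if (is.na(cc)) 0 else cc,
              if (is.na(st$separability)) 0 else st$separability)
        }, numeric(3))
        zd <- .permZ(obs$density, nullMat[1L, ])
        zc <- .permZ(obsConn, nullMat[2L, ])
        zs <- .permZ(if (is.na(obs$separability)) 0 else obs$separability,
                     nullMat[3L, ])
        data.frame(module = m, size = s, Z_density = zd,
                   Z_connectivity = zc, Z_separability = zs,
                   Z_summary = .zSummary(zd, zc), n_permutations = nPerm)
    })
    do.call(rbind, rows)
}

#' Cross-network module preservation Z statistics
#'
#' Evaluates whether modules detected in a reference network retain their
#' structure in a test network, following the permutation-Z convention:
#' Z < 2 poor, 2-10 moderate, > 10 high preservation. Per reference module
#' (restricted to genes shared by both networks):
#' \itemize{
#'   \item density statistic: mean test-network adjacency among the module
#'     genes;
#'   \item connectivity statistic: the mean of `cor.kIM` (correlation of
#'     intramodular connectivities in ref vs test) and `cor.adj`
#'     (correlation of the within-module adjacency entries);
#'   \item separability on the test network.
#' }
#' Z scores are computed against `nPerm` random same-size gene sets and
#' `Z_summary = (Z_density + Z_connectivity) / 2`.
#'
#' @param ref,test [GeneNetwork]s; the test network is restricted to genes
#'   shared with the reference.
#' @param refModules Module labels detected in `ref`.
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @return data.frame as in [moduleQuality()]; modules with fewer than 3
#'   shared genes get `NA` with a warning.
#' @export
modulePreservation <- function(ref, test, refModules, nPerm = 200L, seed) {
    if (missing(seed))
        stop("a seed is required for the permutation null")
    if (nPerm < 1L)
        stop("nPerm must be positive (cannot form a permutation null)")
    shared <- intersect(geneIds(ref), geneIds(test))
    if (length(shared) == 0L)
        stop("reference and test networks share no genes")
    message(length(shared), " genes shared between reference and test ",
            "networks")
    aRef <- adjacency(ref)[match(shared, geneIds(ref)),
                           match(shared, geneIds(ref))]
    aTest <- adjacency(test)[match(shared, geneIds(test)),
                             match(shared, geneIds(test))]
    modules <- refModules[shared]
    labs <- setdiff(unique(modules[!is.na(modules)]), "unassigned")
    statsFor <- function(idx) {
        stRef <- .moduleStats(aRef, idx)
        stTest <- .moduleStats(aTest, idx)
        corKIM <- suppressWarnings(stats::cor(stRef$kim, stTest$kim))
        subR <- .lowerTri(aRef[idx, idx, drop = FALSE])
        subT <- .lowerTri(aTest[idx, idx, drop = FALSE])
        corAdj <- suppressWarnings(stats::cor(subR, subT))
        connStat <- mean(c(if (is.na(corKIM)) 0 else corKIM,
                           if (is.na(corAdj)) 0 else corAdj))
        c(density = stTest$density, connectivity = connStat,
          separability = if (is.na(stTest$separability)) 0
                         else stTest$separability)
    }
    rows <- lapply(labs, function(m) {
        idx <- which(modules == m)
        s <- length(idx)
        if (s < 3L) {
            warning("module ", m, " has fewer than 3 shared genes")
            return(data.frame(module = m, size = s, Z_density = NA_real_,
                              Z_connectivity = NA_real_,
                              Z_separability = NA_real_,
                              Z_summary = NA_real_,
                              n_permutations = nPerm))
        }
        obs <- statsFor(idx)
        sets <- .nullSets(shared, s, nPerm, seed)
        nullMat <- vapply(sets, function(gset)
            statsFor(match(gset, shared)), numeric(3))
        zd <- .permZ(obs["density"], nullMat[1L, ])
        zc <- .permZ(obs["connectivity"], nullMat[2L, ])
        zs <- .permZ(obs["separability"], nullMat[3L, ])
        data.frame(module = m, size = s, Z_density = zd,
                   Z_connectivity = zc, Z_separability = zs,
                   Z_summary = .zSummary(zd, zc), n_permutations = nPerm)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a module assignment or preservation report as TSV
#'
#' @param x Module labels (named character) or a preservation/quality
#'   data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeModuleTable <- function(x, path) {
    if (is.character(x))
        x <- data.frame(gene_id = names(x), module = unname(x))
    data.table::fwrite(x, path, sep = "\t")
    invisible(path)
}
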