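#' Jaccard overlap of two TFBS sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty. A gene pair
#' is flagged as sharing TFBS when the value is strictly greater than 0.5,
#' i.e. the intersection holds at least half of all sites detected in the
#' two genes.
#'
#' @param setA,setB Character vectors of factor ids.
#' @return List with `jaccard` in `[0, 1]` and logical `shared`.
#' @export
tfbsJaccard <- function(setA, setB) {
    setA <- unique(setA)
    setB <- unique(setB)
    u <- length(union(setA, setB))
    j <- if (u == 0L) 0 else length(intersect(setA, setB)) / u
    list(jaccard = j, shared = j > 0.5)
}

#' Canberra distance between two SFBS multiplicity vectors
#'
#' The splicing-factor binding-site profile of a gene is a length-21
#' non-negative integer vector (one multiplicity per splicing factor, fixed
#' order). The Canberra distance between two profiles lies in `[0, 21]`;
#' terms with both entries zero contribute 0.
#'
#' @param vecA,vecB Length-21 non-negative numeric vectors.
#' @return Distance in `[0, 21]`.
#' @export
sfbsDistance <- function(vecA, vecB) {
    if (length(vecA) != 21L || length(vecB) != 21L)
        stop("SFBS vectors must have length 21")
    if (any(vecA < 0) || any(vecB < 0))
        stop("SFBS multiplicities must be non-negative")
    den <- vecA + vecB
    terms <- abs(vecA - vecB) / den
    terms[den == 0] <- 0
    sum(terms)
}

#' Gene pairs with a shared TFBS profile
#'
#' All unordered gene pairs whose TFBS Jaccard overlap exceeds 0.5.
#'
#' @param bundle An [AnnotationBundle] with a `tfbs` component.
#' @return Two-column character matrix of gene pairs.
#' @export
tfbsSharedPairs <- function(bundle) {
    sets <- bundle@tfbs
    genes <- names(sets)
    out <- list()
    n <- length(genes)
    for (i in seq_len(max(n - 1L, 0L)))
        for (j in (i + 1L):n)
            if (tfbsJaccard(sets[[i]], sets[[j]])$shared)
                out[[length(out) + 1L]] <- c(genes[i], genes[j])
    if (!length(out))
        return(matrix(character(0), ncol = 2))
    .asPairMatrix(do.call(rbind, out))
}

#' Gene pairs with similar SFBS profiles
#'
#' Computes the Canberra distance between every pair of per-gene SFBS
#' vectors and flags pairs below `threshold` as sharing SFBS. By default the
#' threshold is the empirical lower quartile of all pair distances (a
#' dataset-specific quantity; on the mouse striatum data this was < 7.6).
#'
#' @param bundle An [AnnotationBundle] with an `sfbs` matrix (genes x 21).
#' @param threshold Distance threshold; `NULL` (default) uses the empirical
#'   lower quartile.
#' @return List with `pairs` (two-column matrix), `threshold` used and the
#'   full `distances` data.frame.
#' @export
sfbsSharedPairs <- function(bundle, threshold = NULL) {
    m <- bundle@sfbs
    genes <- rownames(m)
    n <- nrow(m)
    if (n < 2L)
        stop("need at least 2 SFBS vectors")
    ii <- jj <- integer(0)
    dd <- numeric(0)
    for (i in seq_len(n - 1L)) {
        rest <- (i + 1L):n
        den <- sweep(m[rest, , drop = FALSE], 2L, m[i, ], `+`)
        num <- abs(sweep(m[rest, , drop = FALSE], 2L, m[i, ], `-`))
        terms <- num / den
        terms[den == 0] <- 0
        d <- rowSums(terms)
        ii <- c(ii, rep(i, length(rest)))
        jj <- c(jj, rest)
        dd <- c(dd, d)
    }
    if (is.null(threshold))
        threshold <- stats::quantile(dd, 0.25, names = FALSE)
    keep <- dd < threshold
    pairs <- cbind(genes[ii[keep]], genes[jj[keep]])
    list(pairs = .asPairMatrix(pairs), threshold = threshold,
         distances = data.frame(gene_a = genes[ii], gene_b = genes[jj],
                                distance = dd))
}

#' Gene pairs sharing microRNA binding sites
#'
#' All unordered gene pairs whose microRNA site sets share at least
#' `minShared` sites (default 2).
#'
#' @param bundle An [AnnotationBundle] with a `mirna` component.
#' @param minShared Minimum number of shared sites.
#' @return Two-column character matrix of gene pairs.
#' @export
sharedMirnaPairs <- function(bundle, minShared = 2L) {
    sets <- lapply(bundle@mirna, unique)
    genes <- names(sets)
    n <- length(genes)
    out <- list()
    for (i in seq_len(max(n - 1L, 0L)))
        for (j in (i + 1L):n)
            if (length(intersect(sets[[i]], sets[[j]])) >= minShared)
                out[[length(out) + 1L]] <- c(genes[i], genes[j])
    if (!length(out))
        return(matrix(character(0), ncol = 2))
    .asPairMatrix(do.call(rbind, out))
}

#' Colocalization gene pairs
#'
#' Pairs formed when either gene lists the other among its spatially
#' colocalized neighbors.
#'
#' @param bundle An [AnnotationBundle] with a `colocal` component.
#' @return Two-column character matrix of gene pairs.
#' @export
colocalPairs <- function(bundle) {
    lst <- bundle@colocal
    if (!length(lst))
        return(matrix(character(0), ncol = 2))
    pairs <- do.call(rbind, lapply(names(lst), function(g)
        if (length(lst[[g]])) cbind(g, lst[[g]]) else NULL))
    if (is.null(pairs))
        return(matrix(character(0), ncol = 2))
    .asPairMatrix(pairs)
}

## Extract edge weights for a set of gene pairs from a network.
.pairWeights <- function(net, pairs, scale) {
    pairs <- .asPairMatrix(pairs)
    g <- geneIds(net)
    keep <- pairs[, 1L] %in% g & pairs[, 2L] %in% g
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L)
        return(numeric(0))
    w <- if (scale == "correlation") netCorrelation(net) else adjacency(net)
    w[cbind(match(pairs[, 1L], g), match(pairs[, 2L], g))]
}

## All unordered non-self index pairs of n genes, as a 2-column matrix of
## linear pair indices (used for random backgrounds).
.samplePairs <- function(genes, size, exclude = NULL) {
    n <- length(genes)
    total <- n * (n - 1) / 2
    size <- min(size, total)
    take <- sample.int(total, size)
    ## map linear lower-triangle index (column-major) to (i, j), i > j
    j <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * take))
    off <- take - (j - 1) * n + (j - 1) * j / 2
    i <- j + off
    pairs <- cbind(genes[pmin(i, j)], genes[pmax(i, j)])
    if (!is.null(exclude) && nrow(exclude)) {
        bad <- .pairKey(pairs[, 1L], pairs[, 2L]) %in%
            .pairKey(exclude[, 1L], exclude[, 2L])
        pairs <- pairs[!bad, , drop = FALSE]
    }
    pairs
}

#' Edge-weight shift for a gene-pair group
#'
#' Quantifies how much stronger (or weaker) the network edges of a group of
#' gene pairs are compared with a background, e.g. pairs with a known
#' protein-protein interaction vs random pairs. Edge weights are taken on
#' the correlation scale by default (pre-soft-threshold, where shifts of
#' 0.03-0.14 are meaningful). Reports the Hodges-Lehmann shift (median of
#' all pairwise group-minus-background differences), a 95% percentile
#' bootstrap confidence interval obtained by resampling pairs within each
#' group, and the two-sided Mann-Whitney p-value.
#'
#' @param net A [GeneNetwork].
#' @param pairGroup Two-column matrix/data.frame of gene pairs.
#' @param background Two-column matrix of pairs, or `"random"` for a seeded
#'   uniform sample of gene pairs (default size 10x the group, group pairs
#'   excluded, drawn without replacement).
#' @param nBoot Bootstrap replicates (0 gives a missing CI).
#' @param seed Integer seed (mandatory when `background = "random"` or
#'   `nBoot > 0`).
#' @param scale `"correlation"` (default) or `"adjacency"`.
#' @param backgroundFactor Background size as a multiple of the group size.
#' @param factorName Label carried into the result.
#' @return List (`ShiftResult`): `factor`, `flavor`, `shift`, `ci_low`,
#'   `ci_high`, `p_value`, `n_group`, `n_background`.
#' @export
edgeWeightShift <- function(net, pairGroup, background = "random",
                            nBoot = 1000L, seed = NULL,
                            scale = c("correlation", "adjacency"),
                            backgroundFactor = 10, factorName = "factor") {
    scale <- match.arg(scale)
    pairGroup <- .asPairMatrix(pairGroup)
    wg <- .pairWeights(net, pairGroup, scale)
    if (length(wg) == 0L)
        stop("no group pairs fall within the network genes")
    if (identical(background, "random")) {
        if (is.null(seed))
            stop("a seed is required for a random background")
        bg <- .withSeed(seed,
            .samplePairs(geneIds(net),
                         ceiling(backgroundFactor * length(wg)),
                         exclude = pairGroup))
    } else {
        bg <- .asPairMatrix(background)
    }
    wb <- .pairWeights(net, bg, scale)
    if (length(wb) == 0L)
        stop("no background pairs fall within the network genes")
    shift <- .hodgesLehmann(wg, wb)
    p <- suppressWarnings(
        stats::wilcox.test(wg, wb, exact = FALSE)$p.value)
    ciLow <- ciHigh <- NA_real_
    if (nBoot > 0L) {
        if (is.null(seed))
            stop("a seed is required for the bootstrap CI")
        boots <- .withSeed(seed + 1L, vapply(seq_len(nBoot), function(b) {
            .hodgesLehmann(wg[sample.int(length(wg), replace = TRUE)],
                           wb[sample.int(length(wb), replace = TRUE)])
        }, numeric(1)))
        ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
        ciLow <- ci[1L]
        ciHigh <- ci[2L]
    }
    list(factor = factorName, flavor = netFlavor(net), shift = shift,
         ci_low = ciLow, ci_high = ciHigh, p_value = p,
         n_group = length(wg), n_background = length(wb))
}

#' Same-domain vs distance-matched cross-domain comparison
#'
#' Compares edge weights of gene pairs lying in the same chromosomal folding
#' domain against cross-domain pairs on the same chromosome whose genomic
#' (midpoint) separation matches a same-domain pair's separation within
#' `bpTolerance` (relative). Matching is greedy over pairs sorted by
#' separation, each control used once, so it is deterministic and invariant
#' to gene-id relabeling.
#'
#' @param net A [GeneNetwork].
#' @param bundle An [AnnotationBundle] with a `domains` table covering
#'   network genes.
#' @param bpTolerance Relative distance-match tolerance (default 0.2).
#' @param nBoot,seed,scale Passed to [edgeWeightShift()].
#' @return A `ShiftResult` list as in [edgeWeightShift()], plus `n_matched`.
#' @export
domainMatchedComparison <- function(net, bundle, bpTolerance = 0.2,
                                    nBoot = 1000L, seed = NULL,
                                    scale = c("correlation", "adjacency")) {
    scale <- match.arg(scale)
    dom <- bundle@domains
    dom <- dom[dom$gene_id %in% geneIds(net), , drop = FALSE]
    if (nrow(dom) < 3L)
        stop("domain table covers fewer than 3 network genes")
    mid <- (dom$start + dom$end) / 2
    sameDist <- ctlDist <- numeric(0)
    samePair <- ctlPair <- list()
    for (chrom in unique(dom$chrom)) {
        idx <- which(dom$chrom == chrom)
        if (length(idx) < 2L) next
        for (a in seq_len(length(idx) - 1L)) {
            for (b in (a + 1L):length(idx)) {
                i <- idx[a]; j <- idx[b]
                d <- abs(mid[i] - mid[j])
                pr <- c(dom$gene_id[i], dom$gene_id[j])
                if (dom$domain_id[i] == dom$domain_id[j]) {
                    sameDist <- c(sameDist, d)
                    samePair[[length(samePair) + 1L]] <- pr
                } else {
                    ctlDist <- c(ctlDist, d)
                    ctlPair[[length(ctlPair) + 1L]] <- pr
                }
            }
        }
    }
    if (!length(samePair))
        stop("no same-domain gene pairs found")
    if (!length(ctlPair))
        stop("no cross-domain control pairs found (all genes share a domain)")
    ## greedy matching on separation, smallest group separation first
    ogrp <- order(sameDist)
    octl <- order(ctlDist)
    ctlSorted <- ctlDist[octl]
    used <- rep(FALSE, length(ctlSorted))
    gsel <- integer(0); csel <- integer(0)
    for (g in ogrp) {
        tol <- bpTolerance * sameDist[g]
        cand <- which(!used & abs(ctlSorted - sameDist[g]) <= tol)
        if (!length(cand)) next
        best <- cand[which.min(abs(ctlSorted[cand] - sameDist[g]))]
        used[best] <- TRUE
        gsel <- c(gsel, g)
        csel <- c(csel, octl[best])
    }
    if (!length(gsel)) {
        strata <- stats::quantile(sameDist, c(0, .25, .5, .75, 1))
        stop("no distance-matchable cross-domain controls; same-domain ",
             "separation quartiles: ",
             paste(signif(strata, 3), collapse = ", "))
    }
    if (length(gsel) < length(sameDist))
        warning(length(sameDist) - length(gsel),
                " same-domain pair(s) had no matchable control and were ",
                "dropped")
    grp <- do.call(rbind, samePair[gsel])
    ctl <- do.call(rbind, ctlPair[csel])
    res <- edgeWeightShift(net, grp, background = ctl, nBoot = nBoot,
                           seed = seed, scale = scale,
                           factorName = "chromosomal_domain")
    res$n_matched <- length(gsel)
    res
}

## ---- annotation table readers ----

#' Read edge-factor annotation tables
#'
#' Readers for the plain-text annotation formats consumed by the
#' edge-factor analyses:
#' \itemize{
#'   \item PPI: two-column TSV of gene pairs (no header required; a
#'     `gene_a`/`gene_b` header line is tolerated).
#'   \item TFBS / microRNA / colocalization: TSV `gene_id<TAB>` followed by
#'     a comma-separated id list.
#'   \item SFBS: TSV `gene_id` plus 21 numeric multiplicity columns.
#'   \item Domains: BED-like TSV `gene_id, chrom, start, end, domain_id`
#'     with 0-based half-open intervals.
#' }
#'
#' @param path Input file.
#' @return The component in the representation used by [AnnotationBundle].
#' @name annotationReaders
NULL

#' @rdname annotationReaders
#' @export
readPpiPairs <- function(path) {
    dt <- data.table::fread(path, header = "auto", data.table = FALSE,
                            colClasses = "character")
    .asPairMatrix(as.matrix(dt[, 1:2]))
}

.readIdListTable <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, colClasses = "character")
    sets <- strsplit(dt[[2L]], ",", fixed = TRUE)
    sets <- lapply(sets, trimws)
    names(sets) <- dt[[1L]]
    sets
}

#' @rdname annotationReaders
#' @export
readTfbsSets <- function(path) .readIdListTable(path)

#' @rdname annotationReaders
#' @export
readMirnaSites <- function(path) .readIdListTable(path)

#' @rdname annotationReaders
#' @export
readColocalization <- function(path) .readIdListTable(path)

#' @rdname annotationReaders
#' @export
readSfbsVectors <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- dt[[1L]]
    if (ncol(m) != 21L)
        stop("SFBS table must have 21 multiplicity columns")
    m
}

#' @rdname annotationReaders
#' @export
readDomainTable <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "domain_id")
    if (!all(need %in% colnames(dt)))
        stop("domain table needs columns: ", paste(need, collapse = ", "))
    dt
}
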