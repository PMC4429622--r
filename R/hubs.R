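#' Select network-exclusive hub genes
#'
#' Hubs specific to network A: genes whose connectivity in A is at or above
#' the `1 - topQ` quantile of `kA` AND whose connectivity in B is at or
#' below the `lowQ` quantile of `kB`. The defaults (top 10% of A, bottom
#' 80% of B) select hubs of one network that are not even moderately
#' connected in the other; the stricter preset `lowQ = 0.10` selects highly
#' exclusive hubs. Quantiles are empirical with linear interpolation and
#' both thresholds are inclusive (ties kept).
#'
#' @param kA,kB Named connectivity vectors over the identical gene set.
#' @param topQ Top quantile fraction in A (default 0.10).
#' @param lowQ Low quantile fraction in B (default 0.80).
#' @return List with `genes` (character), `rule` (the thresholds used) and
#'   the two cutoffs.
#' @export
selectExclusiveHubs <- function(kA, kB, topQ = 0.10, lowQ = 0.80) {
    if (topQ <= 0 || topQ >= 1 || lowQ <= 0 || lowQ >= 1)
        stop("quantile fractions must lie strictly in (0, 1)")
    if (length(kA) != length(kB) ||
        !setequal(names(kA), names(kB)))
        stop("kA and kB must cover identical gene lists")
    kB <- kB[names(kA)]
    hi <- stats::quantile(kA, 1 - topQ, names = FALSE)
    lo <- stats::quantile(kB, lowQ, names = FALSE)
    genes <- names(kA)[kA >= hi & kB <= lo]
    list(genes = genes,
         rule = c(top_q = topQ, low_q = lowQ),
         cutoff_top = hi, cutoff_low = lo)
}

#' Map cross-hub edges onto whole-network edge quartiles
#'
#' Quartile breakpoints are computed over ALL off-diagonal edge weights of
#' the network; every edge between a hub of set A and a hub of set B is then
#' assigned to a quartile. An edge equal to a breakpoint goes to the upper
#' quartile (inclusive-upper convention), so degenerate all-equal networks
#' place every edge in the fourth quartile. Strong cross-hub edges landing
#' in the top quartile indicate that the network couples the two hub types.
#'
#' @param net A [GeneNetwork]; edge weights are taken from the adjacency.
#' @param hubsA,hubsB Hub sets (from [selectExclusiveHubs()] or character
#'   vectors); must be disjoint and non-empty.
#' @param scale `"adjacency"` or `"correlation"` edge weights.
#' @return Named integer vector of length 4 (`Q1`..`Q4`) summing to
#'   `|A| * |B|`.
#' @export
crossHubEdgeQuartiles <- function(net, hubsA, hubsB,
                                  scale = c("adjacency", "correlation")) {
    scale <- match.arg(scale)
    if (is.list(hubsA)) hubsA <- hubsA$genes
    if (is.list(hubsB)) hubsB <- hubsB$genes
    if (length(hubsA) == 0L || length(hubsB) == 0L)
        stop("hub sets must be non-empty")
    if (length(intersect(hubsA, hubsB)))
        stop("hub sets must be disjoint")
    w <- if (scale == "adjacency") adjacency(net) else netCorrelation(net)
    all <- .lowerTri(w)
    q <- stats::quantile(all, c(0.25, 0.5, 0.75), names = FALSE)
    ia <- .geneIndex(net, hubsA, "hub-A genes")
    ib <- .geneIndex(net, hubsB, "hub-B genes")
    cross <- as.vector(w[ia, ib, drop = FALSE])
    bin <- 1L + (cross >= q[1L]) + (cross >= q[2L]) + (cross >= q[3L])
    counts <- tabulate(bin, nbins = 4L)
    names(counts) <- paste0("Q", 1:4)
    counts
}

#' Fisher exact gene-set enrichment
#'
#' Hypergeometric test of the overlap between two gene sets within a fixed
#' universe. Returns the 2x2 table, the odds ratio, the exact one-sided
#' (enrichment) p-value and the two-sided Fisher p-value.
#'
#' @param set1,set2 Gene id vectors (subsets of `universe`), or single
#'   integers giving set sizes when `overlap` is supplied.
#' @param universe Gene id vector, or a single integer universe size when
#'   counts are given directly.
#' @param overlap Optional integer overlap, for the counts-only interface.
#' @return List with `table` (2x2 matrix), `odds_ratio`, `p_one_sided`,
#'   `p_two_sided`, `universe_size`.
#' @examples
#' fisherEnrichment(425, 660, 9066, overlap = 65)$p_one_sided
#' @export
fisherEnrichment <- function(set1, set2, universe, overlap = NULL) {
    if (is.null(overlap)) {
        set1 <- unique(as.character(set1))
        set2 <- unique(as.character(set2))
        universe <- unique(as.character(universe))
        if (length(universe) == 0L)
            stop("universe must be non-empty")
        if (!all(set1 %in% universe) || !all(set2 %in% universe))
            stop("set1 and set2 must be subsets of the universe")
        n <- length(universe)
        n1 <- length(set1)
        n2 <- length(set2)
        k <- length(intersect(set1, set2))
    } else {
        n1 <- as.integer(set1)
        n2 <- as.integer(set2)
        n <- as.integer(universe)
        k <- as.integer(overlap)
        if (n <= 0L)
            stop("universe must be non-empty")
        if (k > min(n1, n2) || n1 > n || n2 > n)
            stop("inconsistent counts")
    }
    tab <- matrix(c(k, n1 - k, n2 - k, n - n1 - n2 + k), nrow = 2,
                  dimnames = list(set1 = c("in", "out"),
                                  set2 = c("in", "out")))
    if (any(tab < 0))
        stop("inconsistent counts: negative cell in the 2x2 table")
    pOne <- stats::phyper(k - 1, n1, n - n1, n2, lower.tail = FALSE)
    ft <- stats::fisher.test(tab)
    list(table = tab, odds_ratio = unname(ft$estimate),
         p_one_sided = pOne, p_two_sided = ft$p.value,
         universe_size = n)
}

#' Compare hub characteristics between two gene groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on a per-gene numeric
#' annotation (e.g. exon count, transcript count, coding length, GC%,
#' coefficient of variation of gene totals), plus the Hodges-Lehmann shift
#' estimate (the median of all pairwise differences `A - B`).
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return List with `p_value` (two-sided) and `shift` (HL estimate of the
#'   location of A relative to B).
#' @export
compareHubCharacteristics <- function(groupA, groupB) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("both groups need at least 2 values")
    p <- suppressWarnings(
        stats::wilcox.test(groupA, groupB, exact = FALSE)$p.value)
    list(p_value = p, shift = .hodgesLehmann(groupA, groupB))
}

#' Coefficient of variation of gene totals
#'
#' sd/mean of each gene's per-sample exon-summed totals, a hub
#' characteristic distinguishing coexpression hubs (high CV) from
#' cosplicing hubs.
#'
#' @param x An [ExonCounts].
#' @return Named numeric vector per gene.
#' @export
geneCountCV <- function(x) {
    tot <- geneTotals(x)
    mu <- rowMeans(tot)
    s <- apply(tot, 1L, stats::sd)
    cv <- ifelse(mu > 0, s / mu, NA_real_)
    names(cv) <- rownames(tot)
    cv
}

#' Read a gene set (plain text or GMT)
#'
#' Plain text: one gene id per line. GMT: tab-separated `name`,
#' `description`, genes...; returns a named list of sets.
#'
#' @param path Input file.
#' @param format `"auto"`, `"list"` or `"gmt"`.
#' @return Character vector (list format) or named list (GMT).
#' @export
readGeneSet <- function(path, format = c("auto", "list", "gmt")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
                  else "list"
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (format == "list")
        return(trimws(lines))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    sets
}
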