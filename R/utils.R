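## Internal helpers shared across modules.

## Canonical unordered pair key "a|b" with a < b; used to deduplicate and
## intersect gene-pair sets.
.pairKey <- function(a, b) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    paste(lo, hi, sep = "\r")
}

## Normalise a gene-pair set (2-column matrix / data.frame) to a
## deduplicated 2-column character matrix with self-pairs dropped.
.asPairMatrix <- function(pairs) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L)
        stop("a gene-pair set must have exactly two columns")
    storage.mode(pairs) <- "character"
    keep <- pairs[, 1L] != pairs[, 2L]
    pairs <- pairs[keep, , drop = FALSE]
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    pairs[!duplicated(.pairKey(pairs[, 1L], pairs[, 2L])), , drop = FALSE]
}

## Lower-triangle (column-major, i > j) of a symmetric matrix as a vector.
.lowerTri <- function(m) m[lower.tri(m)]

## Hodges-Lehmann two-sample shift: median of all pairwise differences
## x_i - y_j. Exact; O(len(x) * len(y)) memory, fine at the sizes used here.
.hodgesLehmann <- function(x, y) {
    stats::median(rep(x, times = length(y)) -
                  rep(y, each = length(x)))
}

## Evaluate `expr` under a temporary RNG seed, restoring the caller's
## RNG state afterwards.
.withSeed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}

## Z score against a permutation null. A degenerate null (sd ~ 0) makes the
## Z undefined (0/0) when the observation matches the null -- reported as NA
## and excluded from summaries -- and +/-Inf when it does not.
.permZ <- function(observed, nullValues) {
    mu <- mean(nullValues)
    s <- stats::sd(nullValues)
    if (!is.finite(s) || s < 1e-12) {
        if (abs(observed - mu) < 1e-12)
            return(NA_real_)
        return(sign(observed - mu) * Inf)
    }
    (observed - mu) / s
}

## Mean of the defined permutation Zs (NA components carry no information).
.zSummary <- function(zd, zc) {
    if (is.na(zd) && is.na(zc)) NA_real_ else mean(c(zd, zc), na.rm = TRUE)
}

## Adjusted Rand index between two label vectors (Hubert & Arabie).
.adjustedRand <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    n <- length(a)
    sum2 <- function(v) sum(v * (v - 1) / 2)
    sij <- sum2(as.vector(tab))
    si <- sum2(rowSums(tab))
    sj <- sum2(colSums(tab))
    tot <- n * (n - 1) / 2
    expected <- si * sj / tot
    mx <- (si + sj) / 2
    if (abs(mx - expected) < .Machine$double.eps)
        return(0)
    (sij - expected) / (mx - expected)
}

## Index of genes (character) in a network, erroring on misses.
.geneIndex <- function(net, genes, what = "genes") {
    idx <- match(genes, geneIds(net))
    if (anyNA(idx))
        stop(sum(is.na(idx)), " ", what, " not present in the network")
    idx
}
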