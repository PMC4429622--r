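#' Read an exon-level count table
#'
#' Reads a tab-separated text file (gzip-transparent) with header columns
#' `gene_id`, `exon_id`, then one column per sample, into an [ExonCounts]
#' object. Samples keep their file order; exon order within a gene is the
#' file order.
#'
#' @param path Path to the TSV file (may be `.gz`).
#' @return An [ExonCounts].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\texon_id\ts1\ts2",
#'              "g1\te1\t5\t2", "g1\te2\t0\t7", "g2\te1\t1\t3"), tf)
#' readExonCounts(tf)
#' @export
readExonCounts <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1:2),
                            data.table = FALSE)
    if (ncol(dt) < 3L ||
        !identical(colnames(dt)[1:2], c("gene_id", "exon_id")))
        stop("expected header: gene_id<TAB>exon_id<TAB><sample columns>")
    sampleCols <- colnames(dt)[-(1:2)]
    nonnum <- !vapply(dt[-(1:2)], is.numeric, logical(1))
    if (any(nonnum)) {
        col <- sampleCols[which(nonnum)[1L]]
        row <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1L]
        stop("non-numeric count at row ", row, ", sample '", col, "'")
    }
    cts <- as.matrix(dt[, -(1:2), drop = FALSE])
    if (anyNA(cts)) {
        idx <- which(is.na(cts), arr.ind = TRUE)[1L, ]
        stop("missing/non-numeric count at row ", idx[1L],
             ", sample '", sampleCols[idx[2L]], "'")
    }
    if (any(cts < 0)) {
        idx <- which(cts < 0, arr.ind = TRUE)[1L, ]
        stop("negative count at gene '", dt$gene_id[idx[1L]],
             "', exon '", dt$exon_id[idx[1L]],
             "', sample '", sampleCols[idx[2L]], "'")
    }
    key <- paste(dt$gene_id, dt$exon_id, sep = "\r")
    if (anyDuplicated(key)) {
        d <- key[duplicated(key)][1L]
        stop("duplicated (gene_id, exon_id) row: ",
             gsub("\r", ", ", d, fixed = TRUE))
    }
    colnames(cts) <- sampleCols
    ExonCounts(cts, geneId = dt$gene_id, exonId = dt$exon_id)
}

#' Write an exon-level count table
#'
#' Writes an [ExonCounts] back to the TSV dialect read by
#' [readExonCounts()].
#'
#' @param x An [ExonCounts].
#' @param path Output path; a `.gz` suffix gives gzip output.
#' @return `path`, invisibly.
#' @export
writeExonCounts <- function(x, path) {
    rd <- SummarizedExperiment::rowData(x)
    dt <- data.frame(gene_id = rd$gene_id, exon_id = rd$exon_id,
                     counts(x), check.names = FALSE)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Per-sample gene totals
#'
#' Sums exon counts within each gene (the union-exon gene total) for every
#' sample.
#'
#' @param x An [ExonCounts].
#' @return Numeric matrix, genes x samples, rows in [geneIds()] order.
#' @export
geneTotals <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    tot <- rowsum(counts(x), group = rd$gene_id, reorder = FALSE)
    tot[geneIds(x), , drop = FALSE]
}

#' Upper-quartile normalization
#'
#' Scales each sample by its upper-quartile normalization factor: per
#' sample, gene totals (exon-summed) are computed; the raw factor is the
#' 75th percentile of the nonzero gene totals divided by the library size
#' (total counts); factors are then divided by their geometric mean. Each
#' sample's counts are divided by `library size x factor` and multiplied by
#' the mean library size, uniformly over all exons of the sample.
#'
#' @param x An [ExonCounts].
#' @return A list with elements `counts` (the normalized [ExonCounts]) and
#'   `factors` (data.frame with `sample`, `library_size`, `scale_factor`;
#'   the factors have geometric mean 1).
#' @examples
#' ec <- simulateExonCounts(simConfig(nGenes = 20, nSamples = 4,
#'                                    seed = 1))$counts
#' nf <- upperQuartileNormalize(ec)
#' nf$factors
#' @export
upperQuartileNormalize <- function(x) {
    tot <- geneTotals(x)
    lib <- colSums(tot)
    if (any(lib <= 0))
        stop("all-zero sample(s): ",
             paste(colnames(tot)[lib <= 0], collapse = ", "))
    uq <- vapply(seq_len(ncol(tot)), function(j) {
        v <- tot[, j]
        stats::quantile(v[v > 0], 0.75, names = FALSE)
    }, numeric(1))
    raw <- uq / lib
    f <- raw / exp(mean(log(raw)))
    scale <- mean(lib) / (lib * f)
    cts <- sweep(counts(x), 2L, scale, `*`)
    rd <- SummarizedExperiment::rowData(x)
    list(counts = ExonCounts(cts, geneId = rd$gene_id, exonId = rd$exon_id),
         factors = data.frame(sample = colnames(cts),
                              library_size = unname(lib),
                              scale_factor = unname(f)))
}

#' Remove genes with low average counts
#'
#' A gene is removed iff the mean over samples of its exon-summed total
#' count is strictly below `threshold` (default 500).
#'
#' @param x An [ExonCounts] (normalized or raw; the default pipeline filters
#'   after normalization).
#' @param threshold Non-negative count threshold.
#' @return List with `counts` (filtered [ExonCounts]) and `report` (a
#'   [filterReport()] list).
#' @export
filterLowCountGenes <- function(x, threshold = 500) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        stop("threshold must be a single non-negative number")
    tot <- geneTotals(x)
    meanTot <- rowMeans(tot)
    drop <- names(meanTot)[meanTot < threshold]
    keep <- !(SummarizedExperiment::rowData(x)$gene_id %in% drop)
    report <- filterReport(genesIn = nrow(tot),
                           removedLowCount = length(drop),
                           removedLowConnectivity = 0L)
    list(counts = x[keep, ], report = report, removed = drop)
}

#' Exon network connectivity
#'
#' Connectivity of each exon: the row sum of absolute Pearson correlations
#' with every other exon (self excluded), computed across samples.
#' Zero-variance exons get correlation 0 to all others (with a warning).
#' The exon x exon correlation matrix is computed in column blocks so memory
#' stays bounded; results equal the dense computation exactly.
#'
#' @param x An [ExonCounts].
#' @param blockSize Number of exons per block.
#' @return Numeric vector of per-exon connectivities, in row order.
#' @export
exonConnectivity <- function(x, blockSize = 2000L) {
    m <- t(counts(x))            # samples x exons
    sds <- apply(m, 2L, stats::sd)
    flat <- sds == 0 | !is.finite(sds)
    if (any(flat))
        warning(sum(flat), " zero-variance exon(s); their correlations ",
                "are defined as 0")
    ms <- scale(m)               # centered, unit-sd columns
    ms[, flat] <- 0
    nE <- ncol(ms)
    nS <- nrow(ms)
    k <- numeric(nE)
    for (start in seq(1L, nE, by = blockSize)) {
        idx <- start:min(start + blockSize - 1L, nE)
        cors <- crossprod(ms[, idx, drop = FALSE], ms) / (nS - 1)
        k[idx] <- rowSums(abs(cors)) - 1
    }
    k[flat] <- 0                 # no self term was included for flat exons
    names(k) <- paste(SummarizedExperiment::rowData(x)$gene_id,
                      exonIds(x), sep = ":")
    k
}

#' Remove genes whose exons all have low network connectivity
#'
#' Computes the connectivity of every exon (sum of absolute Pearson
#' correlations to all other exons) and removes a gene iff every one of its
#' exons has connectivity strictly below the bottom-quartile cutoff (the
#' 25th percentile of all exon connectivities).
#'
#' @param x An [ExonCounts] with at least 8 exons.
#' @param blockSize Passed to [exonConnectivity()].
#' @return List with `counts`, `report` and `removed` as in
#'   [filterLowCountGenes()].
#' @export
filterLowConnectivityExons <- function(x, blockSize = 2000L) {
    if (nrow(x) < 8L)
        stop("need at least 8 exons for a meaningful bottom quartile")
    k <- exonConnectivity(x, blockSize = blockSize)
    cutoff <- stats::quantile(k, 0.25, names = FALSE)
    gid <- SummarizedExperiment::rowData(x)$gene_id
    low <- k < cutoff
    allLow <- tapply(low, factor(gid, levels = unique(gid)), all)
    drop <- names(allLow)[allLow]
    keep <- !(gid %in% drop)
    report <- filterReport(genesIn = length(allLow),
                           removedLowCount = 0L,
                           removedLowConnectivity = length(drop))
    list(counts = x[keep, ], report = report, removed = drop)
}

#' Filter report
#'
#' Book-keeping for the gene filters; counts always reconcile:
#' `genes_in = genes_removed_low_count + genes_removed_low_exon_connectivity
#' + genes_retained`.
#'
#' @param genesIn,removedLowCount,removedLowConnectivity Integer counts.
#' @return A list with the four reconciled counts.
#' @export
filterReport <- function(genesIn, removedLowCount = 0L,
                         removedLowConnectivity = 0L) {
    list(genes_in = as.integer(genesIn),
         genes_removed_low_count = as.integer(removedLowCount),
         genes_removed_low_exon_connectivity =
             as.integer(removedLowConnectivity),
         genes_retained = as.integer(genesIn - removedLowCount -
                                     removedLowConnectivity))
}
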