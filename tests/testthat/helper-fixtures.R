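# Fixture builders shared across tests. Everything is generated in code;
# no binary data.

# Small ExonCounts from an explicit matrix.
makeExonCounts <- function(counts, geneId, exonId = NULL) {
    if (is.null(exonId)) {
        exonId <- unlist(lapply(rle(geneId)$lengths, function(k)
            paste0("e", seq_len(k))))
    }
    ExonCounts(counts, geneId = geneId, exonId = exonId)
}

# GeneNetwork straight from a correlation matrix (unit diagonal enforced).
netFromCorrelation <- function(r, beta = 6, flavor = "cosplicex",
                               genes = NULL) {
    if (is.null(genes))
        genes <- if (!is.null(rownames(r))) rownames(r)
                 else sprintf("g%03d", seq_len(nrow(r)))
    diag(r) <- 1
    dimnames(r) <- list(genes, genes)
    new("GeneNetwork", flavor = flavor, beta = beta, geneIds = genes,
        correlation = r, adjacency = abs(r)^beta)
}

# Random symmetric correlation matrix with a planted gene-pair group whose
# correlations are offset; used for edge-shift calibration.
makeShiftFixture <- function(seed, offset = 0, nGenes = 100L,
                             nGroup = 100L, mu = 0.2, sdr = 0.05) {
    withr::with_seed(seed, {
        g <- sprintf("g%03d", seq_len(nGenes))
        r <- matrix(0, nGenes, nGenes)
        v <- pmin(pmax(stats::rnorm(nGenes * (nGenes - 1) / 2, mu, sdr),
                       -0.9), 0.9)
        r[lower.tri(r)] <- v
        r <- r + t(r)
        all <- which(lower.tri(r), arr.ind = TRUE)
        sel <- all[sample(nrow(all), nGroup), ]
        r[sel] <- r[sel] + offset
        r[cbind(sel[, 2L], sel[, 1L])] <- r[sel]
        list(net = netFromCorrelation(r, genes = g),
             pairs = cbind(g[sel[, 2L]], g[sel[, 1L]]))
    })
}

# Block-structured correlation matrix: genes within a block share
# correlation rIn, across blocks rOut.
makeBlockNet <- function(blockSizes, rIn = 0.9, rOut = 0, beta = 6) {
    n <- sum(blockSizes)
    lab <- rep(seq_along(blockSizes), blockSizes)
    r <- matrix(rOut, n, n)
    for (b in seq_along(blockSizes))
        r[lab == b, lab == b] <- rIn
    diag(r) <- 1
    list(net = netFromCorrelation(r, beta = beta), labels = lab)
}

# Write a small exon count TSV and return the path.
writeCountFixture <- function(lines, dir = tempdir()) {
    path <- tempfile(tmpdir = dir, fileext = ".tsv")
    writeLines(lines, path)
    path
}

# Planted-module simulation + the three networks; used by several suites.
buildNetworksFromSim <- function(config) {
    sim <- simulateExonCounts(config)
    norm <- upperQuartileNormalize(sim$counts)
    ec <- filterLowConnectivityExons(
        filterLowCountGenes(norm$counts)$counts)$counts
    list(sim = sim, counts = ec,
         coexpression = buildNetwork(ec, "coexpression", beta = 6),
         cosplicing = buildNetwork(allGeneDistances(ec, "cosine"),
                                   "cosplicing", beta = 6),
         cosplicex = buildNetwork(allGeneDistances(ec, "canberra"),
                                  "cosplicex", beta = 6))
}

# Planted module labels from simulation truth, named by gene.
plantedLabels <- function(sim) {
    tr <- sim$truth$genes
    stats::setNames(ifelse(tr$type == "background", "unassigned",
                           tr$module),
                    tr$gene_id)
}
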