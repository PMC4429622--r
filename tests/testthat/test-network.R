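test_that("Mantel correlation matches brute-force Pearson on fixed triangles", {
    lt <- function(v) {
        m <- matrix(0, 4, 4)
        m[lower.tri(m)] <- v
        m + t(m)
    }
    d1 <- lt(c(1, 2, 3, 4, 5, 6))
    d2 <- lt(c(1, 2, 3, 4, 5, 7))
    expect_equal(mantelCorrelation(d1, d2),
                 cor(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 7)))
    expect_equal(mantelCorrelation(d1, d1), 1)
    expect_equal(mantelCorrelation(d1, 3 * d1), 1)
    expect_equal(mantelCorrelation(d1, -2 * d1), -1)
    expect_warning(z <- mantelCorrelation(lt(rep(2, 6)), d1),
                   "zero variance")
    expect_equal(z, 0)
    expect_error(mantelCorrelation(d1, matrix(0, 3, 3)), "dimensions")
})

test_that("Mantel agrees with vegan on simulated distance matrices", {
    skip_if_not_installed("vegan")
    sim <- simulateExonCounts(simConfig(nGenes = 10, nSamples = 12,
                                        nCoexprModules = 0,
                                        nCospliceModules = 1,
                                        moduleSize = c(5, 5), seed = 6))
    ds <- allGeneDistances(sim$counts, "canberra")
    for (pair in list(c(1, 2), c(3, 9), c(5, 6))) {
        d1 <- distanceMatrix(ds, pair[1])
        d2 <- distanceMatrix(ds, pair[2])
        expect_equal(mantelCorrelation(d1, d2),
                     vegan::mantel(as.dist(d1), as.dist(d2),
                                   permutations = 0)$statistic,
                     tolerance = 1e-12)
    }
})

test_that("network fast path equals the pairwise Mantel loop", {
    sim <- simulateExonCounts(simConfig(nGenes = 50, nSamples = 20,
                                        nCoexprModules = 1,
                                        nCospliceModules = 1,
                                        moduleSize = c(15, 15), seed = 2))
    for (metric in c("canberra", "cosine")) {
        ds <- allGeneDistances(sim$counts, metric)
        flavor <- if (metric == "cosine") "cosplicing" else "cosplicex"
        net <- buildNetwork(ds, flavor, beta = 6)
        r <- netCorrelation(net)
        maxDiff <- 0
        for (i in 1:49) {
            for (j in (i + 1):50) {
                m <- mantelCorrelation(distanceMatrix(ds, i),
                                       distanceMatrix(ds, j))
                maxDiff <- max(maxDiff, abs(m - r[i, j]))
            }
        }
        expect_lt(maxDiff, 1e-10)
        # chunked product equals the single crossproduct
        netChunk <- buildNetwork(ds, flavor, beta = 6, chunk = 7L)
        expect_equal(netCorrelation(netChunk), r, tolerance = 1e-12)
    }
})

test_that("adjacency is the soft-thresholded correlation", {
    r <- matrix(c(1, 0.5, 0.5, 1), 2)
    net <- netFromCorrelation(r, beta = 6)
    expect_equal(adjacency(net)[1, 2], 0.015625)
    expect_equal(adjacency(netFromCorrelation(matrix(c(1, 1, 1, 1), 2),
                                              beta = 6))[1, 2], 1)
    sim <- simulateExonCounts(simConfig(nGenes = 10, nSamples = 8,
                                        nCoexprModules = 0,
                                        nCospliceModules = 0, seed = 1))
    expect_error(buildNetwork(sim$counts, "coexpression", beta = 0),
                 "positive")
    expect_error(buildNetwork(allGeneDistances(sim$counts, "cosine"),
                              "cosplicex"), "metric 'canberra'")
})

test_that("topology statistics match the closed forms", {
    r13 <- 0.5^(1 / 6)   # adjacency 0.5 at beta 6
    r <- matrix(c(1, r13, r13, r13, 1, 0, r13, 0, 1), 3)
    net <- netFromCorrelation(r, beta = 6)
    st <- suppressWarnings(topologyStats(net))
    expect_equal(unname(st$connectivity), c(1.0, 0.5, 0.5))
    expect_equal(st$density, 1 / 3)
    expect_equal(st$centralization, 0.5)
    expect_equal(st$heterogeneity, 0.35355, tolerance = 1e-4)

    # complete graph with equal weights: no centralization, no heterogeneity
    rc <- matrix(0.8, 5, 5)
    stc <- suppressWarnings(topologyStats(netFromCorrelation(rc, beta = 2)))
    expect_equal(stc$centralization, 0)
    expect_equal(stc$heterogeneity, 0, tolerance = 1e-6)
})

test_that("scale-free fit is exactly 1 on a perfect power law", {
    k <- rep(c(2, 5, 8), c(4, 25, 64))   # log f = 2 log k exactly
    expect_equal(scaleFreeFit(k, nBins = 3), 1, tolerance = 1e-9)
})

test_that("scale-free convergence table behaves across powers", {
    fix <- buildNetworksFromSim(simConfig(nGenes = 80, nSamples = 30,
                                          nCoexprModules = 1,
                                          nCospliceModules = 1,
                                          moduleSize = c(25, 25),
                                          seed = 13))
    sc <- scaleFreeConvergence(fix$cosplicex, betas = c(0, 1, 6))
    expect_equal(sc$density[1], 1)                 # beta 0: all-ones
    expect_true(all(diff(sc$mean_k) <= 1e-12))     # non-increasing in beta
    expect_gt(sc$scale_free_r2[3], sc$scale_free_r2[2])
    expect_error(scaleFreeConvergence(fix$cosplicex, betas = c(2, 1)),
                 "sorted")
})

test_that("cosine Mantel is invariant to per-sample gene scaling, Pearson is not", {
    sim <- simulateExonCounts(simConfig(nGenes = 12, nSamples = 16,
                                        nCoexprModules = 0,
                                        nCospliceModules = 1,
                                        moduleSize = c(6, 6), seed = 31))
    ec <- sim$counts
    cts <- counts(ec)
    rows1 <- which(SummarizedExperiment::rowData(ec)$gene_id == "g0001")
    scale <- withr::with_seed(5, exp(rnorm(ncol(cts), 0, 1)))
    cts2 <- cts
    cts2[rows1, ] <- sweep(cts2[rows1, ], 2, scale, `*`)
    ec2 <- makeExonCounts(cts2,
                          geneId = SummarizedExperiment::rowData(ec)$gene_id,
                          exonId = exonIds(ec))
    rCos1 <- netCorrelation(buildNetwork(allGeneDistances(ec, "cosine"),
                                         "cosplicing"))
    rCos2 <- netCorrelation(buildNetwork(allGeneDistances(ec2, "cosine"),
                                         "cosplicing"))
    expect_equal(rCos1, rCos2, tolerance = 1e-9)
    rPea1 <- netCorrelation(buildNetwork(ec, "coexpression"))
    rPea2 <- netCorrelation(buildNetwork(ec2, "coexpression"))
    expect_gt(max(abs(rPea1 - rPea2)), 0.05)
})

test_that("Mantel matrix is invariant to a fixed sample relabeling", {
    sim <- simulateExonCounts(simConfig(nGenes = 10, nSamples = 12,
                                        nCoexprModules = 0,
                                        nCospliceModules = 1,
                                        moduleSize = c(5, 5), seed = 17))
    perm <- withr::with_seed(1, sample(12))
    n1 <- buildNetwork(allGeneDistances(sim$counts, "canberra"),
                       "cosplicex")
    n2 <- buildNetwork(allGeneDistances(sim$counts[, perm], "canberra"),
                       "cosplicex")
    expect_equal(netCorrelation(n1), netCorrelation(n2), tolerance = 1e-12)
})

test_that("edge lists round-trip the network weights", {
    fix <- makeBlockNet(c(4, 4), rIn = 0.6, rOut = 0.1)
    path <- tempfile(fileext = ".tsv")
    writeEdgeList(fix$net, path)
    el <- read.delim(path)
    expect_equal(nrow(el), 8 * 7 / 2)
    expect_equal(sort(unique(round(el$adjacency, 10))),
                 sort(unique(round(c(0.1^6, 0.6^6), 10))))
})
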