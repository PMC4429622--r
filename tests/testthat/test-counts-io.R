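test_that("reading a well-formed table round-trips through write", {
    path <- writeCountFixture(c("gene_id\texon_id\tsA\tsB",
                                "g1\te1\t5\t2",
                                "g1\te2\t0\t7",
                                "g2\te1\t1\t3"))
    ec <- readExonCounts(path)
    expect_s4_class(ec, "ExonCounts")
    expect_identical(geneIds(ec), c("g1", "g2"))
    expect_identical(sampleIds(ec), c("sA", "sB"))
    expect_equal(unname(counts(ec)[2, ]), c(0, 7))

    out <- tempfile(fileext = ".tsv")
    writeExonCounts(ec, out)
    ec2 <- readExonCounts(out)
    expect_equal(counts(ec2), counts(ec))
    expect_identical(exonIds(ec2), exonIds(ec))
})

test_that("malformed tables are rejected with informative errors", {
    neg <- writeCountFixture(c("gene_id\texon_id\tsA\tsB",
                               "g1\te1\t5\t-2"))
    expect_error(readExonCounts(neg), "negative count.*g1.*e1.*sB")

    dup <- writeCountFixture(c("gene_id\texon_id\tsA",
                               "g1\te1\t5",
                               "g1\te1\t6"))
    expect_error(readExonCounts(dup), "duplicated")

    txt <- writeCountFixture(c("gene_id\texon_id\tsA",
                               "g1\te1\tfive"))
    expect_error(readExonCounts(txt), "non-numeric")
})

test_that("upper-quartile factors are 1 for identical samples and scale out", {
    m <- matrix(c(10, 20, 5, 10, 20, 5), ncol = 2)
    ec <- makeExonCounts(m, geneId = c("g1", "g1", "g2"))
    res <- upperQuartileNormalize(ec)
    expect_equal(res$factors$scale_factor, c(1, 1))
    expect_equal(counts(res$counts), counts(ec), ignore_attr = TRUE)

    # sample B = 2 x sample A: totals equalized after normalization
    m2 <- cbind(A = c(10, 20, 5), B = c(20, 40, 10))
    ec2 <- makeExonCounts(m2, geneId = c("g1", "g1", "g2"))
    res2 <- upperQuartileNormalize(ec2)
    tot <- geneTotals(res2$counts)
    expect_equal(tot[, "A"], tot[, "B"], tolerance = 1e-9)

    zero <- makeExonCounts(cbind(A = c(1, 2), B = c(0, 0)),
                           geneId = c("g1", "g2"))
    expect_error(upperQuartileNormalize(zero), "all-zero sample.*B")
})

test_that("upper-quartile factors match an independent step-by-step oracle", {
    withr::with_seed(42, {
        m <- matrix(rpois(30, lambda = rep(c(50, 300, 800), each = 10)),
                    nrow = 10, ncol = 3) + 1
    })
    ec <- makeExonCounts(m, geneId = paste0("g", 1:10),
                         exonId = rep("e1", 10))
    res <- upperQuartileNormalize(ec)

    # oracle: Bullard upper-quartile scaling, computed step by step
    tot <- m
    lib <- colSums(tot)
    uq <- apply(tot, 2, function(v) quantile(v[v > 0], 0.75, names = FALSE))
    raw <- uq / lib
    oracle <- raw / exp(mean(log(raw)))
    expect_equal(res$factors$scale_factor, unname(oracle),
                 tolerance = 1e-12)
    expect_equal(exp(mean(log(res$factors$scale_factor))), 1,
                 tolerance = 1e-9)

    # independent implementation: edgeR's upper-quartile factors
    skip_if_not_installed("edgeR")
    fEdger <- edgeR::calcNormFactors(tot, method = "upperquartile",
                                     p = 0.75)
    expect_equal(res$factors$scale_factor, unname(fEdger),
                 tolerance = 1e-8)
})

test_that("re-normalizing is a fixed point up to one global constant", {
    withr::with_seed(7, {
        m <- matrix(rpois(60, 200) + 1, nrow = 12, ncol = 5)
    })
    ec <- makeExonCounts(m, geneId = rep(paste0("g", 1:4), each = 3))
    once <- upperQuartileNormalize(ec)
    # post-normalization upper quartiles are exactly equal across samples
    tot1 <- geneTotals(once$counts)
    uq1 <- apply(tot1, 2, function(v) quantile(v[v > 0], 0.75,
                                               names = FALSE))
    expect_lt(diff(range(uq1)) / mean(uq1), 1e-9)
    twice <- upperQuartileNormalize(once$counts)
    # the factors do not change (they are scale-free per sample) ...
    expect_equal(twice$factors$scale_factor, once$factors$scale_factor,
                 tolerance = 1e-9)
    # ... and the second pass rescales every cell by one shared constant
    ratio <- counts(twice$counts) / counts(once$counts)
    expect_lt(diff(range(ratio)), 1e-9)
})

test_that("low-count filter removes strictly below the threshold", {
    # gene means over 2 samples: 499, 500, 501, 0
    m <- rbind(c(498, 500), c(500, 500), c(501, 501), c(0, 0))
    ec <- makeExonCounts(m, geneId = paste0("g", 1:4),
                         exonId = rep("e1", 4))
    res <- filterLowCountGenes(ec, threshold = 500)
    expect_setequal(res$removed, c("g1", "g4"))
    expect_identical(geneIds(res$counts), c("g2", "g3"))
    rep <- res$report
    expect_identical(rep$genes_in,
                     rep$genes_removed_low_count +
                     rep$genes_removed_low_exon_connectivity +
                     rep$genes_retained)

    none <- filterLowCountGenes(ec, threshold = 0)
    expect_identical(none$report$genes_retained, 4L)
    expect_error(filterLowCountGenes(ec, threshold = -1), "non-negative")
})

test_that("connectivity filter removes only the all-noise gene", {
    withr::with_seed(3, {
        n <- 20
        shared <- rnorm(n)
        sig <- do.call(rbind, lapply(1:12, function(i)
            1000 + 100 * shared + rnorm(n, 0, 1)))
        noise <- do.call(rbind, lapply(1:4, function(i)
            1000 + rnorm(n, 0, 100)))
    })
    m <- rbind(sig, noise)
    ec <- makeExonCounts(m, geneId = rep(c("g1", "g2", "g3", "gnoise"),
                                         each = 4))
    res <- filterLowConnectivityExons(ec)
    expect_identical(res$removed, "gnoise")
    expect_identical(geneIds(res$counts), c("g1", "g2", "g3"))
    # sample and exon order preserved
    expect_identical(sampleIds(res$counts), sampleIds(ec))
    expect_identical(exonIds(res$counts), exonIds(ec)[1:12])

    # oracle: explicit dense correlation-matrix construction
    k <- exonConnectivity(ec)
    cm <- abs(cor(t(m)))
    expect_equal(unname(k), rowSums(cm) - 1, tolerance = 1e-12)

    # chunked computation equals the dense one exactly
    expect_equal(exonConnectivity(ec, blockSize = 3L), k)
})

test_that("degenerate connectivity cases behave as documented", {
    # all exons identical: every connectivity equal, nothing strictly below
    m <- matrix(rep(c(1, 5, 2, 9), 8), nrow = 8, byrow = TRUE)
    ec <- makeExonCounts(m, geneId = rep(c("g1", "g2"), each = 4))
    res <- filterLowConnectivityExons(ec)
    expect_length(res$removed, 0)

    # zero-variance exon warns but does not error
    m2 <- rbind(matrix(rnorm(28, 100), nrow = 7), rep(3, 4))
    ec2 <- makeExonCounts(m2, geneId = rep(c("g1", "g2"), each = 4))
    expect_warning(exonConnectivity(ec2), "zero-variance")
})

test_that("a gene whose exons copy many other exons is kept", {
    withr::with_seed(9, base <- rnorm(16, 100, 10))
    m <- do.call(rbind, c(replicate(10, base + rnorm(16, 0, 0.1),
                                    simplify = FALSE),
                          replicate(2, rnorm(16, 100, 10),
                                    simplify = FALSE)))
    ec <- makeExonCounts(m, geneId = rep(c("gcopy", "gA", "gB", "gC",
                                           "gD", "gE"), each = 2))
    res <- filterLowConnectivityExons(ec)
    expect_false("gcopy" %in% res$removed)
})
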