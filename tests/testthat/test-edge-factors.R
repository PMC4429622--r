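test_that("TFBS Jaccard overlap and the strict sharing rule", {
    expect_equal(tfbsJaccard(c("A", "B"), c("A", "B")),
                 list(jaccard = 1, shared = TRUE))
    half <- tfbsJaccard(c("A", "B", "C"), c("B", "C", "D"))
    expect_equal(half$jaccard, 0.5)
    expect_false(half$shared)            # strictly greater than 0.5
    expect_equal(tfbsJaccard(c("A"), c("B"))$jaccard, 0)
    expect_equal(tfbsJaccard(character(0), character(0))$jaccard, 0)
})

test_that("SFBS Canberra distance spans [0, 21]", {
    v0 <- rep(0, 21)
    expect_equal(sfbsDistance(v0 + 1, v0 + 1), 0)
    a <- v0; a[1] <- 1
    b <- v0; b[2] <- 1
    expect_equal(sfbsDistance(a, b), 2)
    odd <- v0; odd[seq(1, 21, 2)] <- 3
    even <- v0; even[seq(2, 21, 2)] <- 2
    expect_equal(sfbsDistance(odd, even), 21)   # all positions disjoint
    expect_error(sfbsDistance(1:5, 1:5), "length 21")
})

test_that("pairwise SFBS distances match brute force on exhaustive vectors", {
    # all vectors over {0,1,2}^3 embedded in length-21 profiles
    grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    m <- cbind(grid, matrix(0, nrow(grid), 18))
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    bundle <- AnnotationBundle(sfbs = m)
    res <- sfbsSharedPairs(bundle, threshold = 0.5)
    bf <- function(x, y) {
        s <- 0
        for (i in 1:21) {
            den <- x[i] + y[i]
            if (den > 0) s <- s + abs(x[i] - y[i]) / den
        }
        unname(s)
    }
    d <- res$distances
    for (row in sample(nrow(d), 60)) {
        expect_equal(d$distance[row],
                     bf(m[d$gene_a[row], ], m[d$gene_b[row], ]),
                     tolerance = 1e-12)
    }
    # default threshold is the empirical lower quartile
    resQ <- sfbsSharedPairs(bundle)
    expect_equal(resQ$threshold,
                 quantile(d$distance, 0.25, names = FALSE))
})

test_that("shared-microRNA pairs match brute-force enumeration", {
    bundle <- AnnotationBundle(mirna = list(
        g1 = c("m1", "m2", "m3"),
        g2 = c("m2", "m3"),
        g3 = c("m3"),
        g4 = c("m1", "m2", "m4")))
    pairs <- sharedMirnaPairs(bundle, minShared = 2)
    keys <- cosplicex:::.pairKey(pairs[, 1], pairs[, 2])
    expect_setequal(keys, cosplicex:::.pairKey(c("g1", "g1"),
                                               c("g2", "g4")))
    # exactly two shared sites is included; one shared site is not
    expect_true(cosplicex:::.pairKey("g1", "g2") %in% keys)
    expect_false(cosplicex:::.pairKey("g1", "g3") %in% keys)
})

test_that("edge-weight shift is null for group == background", {
    fx <- makeShiftFixture(5, offset = 0, nGenes = 40, nGroup = 30)
    res <- edgeWeightShift(fx$net, fx$pairs, background = fx$pairs,
                           nBoot = 200, seed = 4)
    expect_equal(res$shift, 0)
    expect_lte(res$ci_low, 0)
    expect_gte(res$ci_high, 0)
})

test_that("a planted correlation offset is recovered with a tight CI", {
    fx <- makeShiftFixture(1, offset = 0.1)
    res <- edgeWeightShift(fx$net, fx$pairs, nBoot = 500, seed = 1)
    expect_gt(res$shift, 0.08)
    expect_lt(res$shift, 0.12)
    expect_gt(res$ci_low, 0)
    expect_lt(res$p_value, 1e-10)

    # nBoot = 0: point estimate only, missing CI
    res0 <- edgeWeightShift(fx$net, fx$pairs, nBoot = 0, seed = 1)
    expect_equal(res0$shift, res$shift)
    expect_true(is.na(res0$ci_low) && is.na(res0$ci_high))

    expect_error(edgeWeightShift(fx$net,
                                 cbind("zz1", "zz2"), seed = 1),
                 "no group pairs")
})

test_that("domain-matched comparison recovers a planted same-domain effect", {
    withr::with_seed(8, {
        n <- 40
        g <- sprintf("g%03d", 1:n)
        # two domains per chromosome, genes spread along the chromosome
        dom <- data.frame(gene_id = g,
                          chrom = rep(c("chr1", "chr2"), each = n / 2),
                          start = rep(seq(0, 1.9e6, length.out = n / 2),
                                      2),
                          domain_id = rep(rep(c("d1", "d2"), each = n / 4),
                                          2))
        dom$end <- dom$start + 1e4
        m <- matrix(rnorm(n * n, 0.1, 0.03), n)
        r <- (m + t(m)) / 2
        dimnames(r) <- list(g, g)
        same <- outer(paste(dom$chrom, dom$domain_id),
                      paste(dom$chrom, dom$domain_id), "==")
        r[same] <- r[same] + 0.1
        diag(r) <- 1
    })
    net <- netFromCorrelation(r, genes = g)
    bundle <- AnnotationBundle(domains = dom)
    expect_warning(
        res <- domainMatchedComparison(net, bundle, nBoot = 300, seed = 2),
        "no matchable control")
    expect_gt(res$shift, 0.05)
    expect_gt(res$ci_low, 0)

    # deterministic under consistent gene-id relabeling
    g2 <- sprintf("x%03d", 1:n)
    r2 <- r
    dimnames(r2) <- list(g2, g2)
    dom2 <- dom
    dom2$gene_id <- g2
    res2 <- suppressWarnings(
        domainMatchedComparison(netFromCorrelation(r2, genes = g2),
                                AnnotationBundle(domains = dom2),
                                nBoot = 300, seed = 2))
    expect_equal(res2$shift, res$shift)
    expect_equal(res2$n_matched, res$n_matched)

    # all genes in one domain: no cross-domain controls
    dom1 <- dom
    dom1$domain_id <- "d1"
    expect_error(domainMatchedComparison(net,
                                         AnnotationBundle(domains = dom1),
                                         seed = 2),
                 "cross-domain")
})

test_that("annotation readers round-trip their formats", {
    ppi <- tempfile(fileext = ".tsv")
    writeLines(c("gene_a\tgene_b", "g1\tg2", "g2\tg1", "g3\tg4"), ppi)
    m <- readPpiPairs(ppi)
    expect_equal(nrow(m), 2)   # deduplicated unordered pairs

    tf <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tfactors", "g1\tA,B", "g2\tB,C"), tf)
    sets <- readTfbsSets(tf)
    expect_identical(sets$g1, c("A", "B"))

    sf <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("gene_id", paste0("f", 1:21)), collapse = "\t"),
                 paste(c("g1", rep("2", 21)), collapse = "\t")), sf)
    sm <- readSfbsVectors(sf)
    expect_identical(dim(sm), c(1L, 21L))

    dm <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tchrom\tstart\tend\tdomain_id",
                 "g1\tchr1\t0\t1000\td1"), dm)
    expect_identical(readDomainTable(dm)$domain_id, "d1")

    co <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tneighbors", "g1\tg2,g3"), co)
    bundle <- AnnotationBundle(colocal = readColocalization(co))
    cp <- colocalPairs(bundle)
    expect_equal(nrow(cp), 2)
})

test_that("pair sets from every factor op are unordered and deduplicated", {
    bundle <- AnnotationBundle(
        tfbs = list(g1 = c("A", "B"), g2 = c("A", "B"), g3 = "C"),
        mirna = list(g1 = c("m1", "m2"), g2 = c("m1", "m2")),
        colocal = list(g1 = "g2", g2 = "g1"))
    for (pairs in list(tfbsSharedPairs(bundle), sharedMirnaPairs(bundle),
                       colocalPairs(bundle))) {
        expect_true(all(pairs[, 1] < pairs[, 2]))
        expect_false(any(duplicated(
            cosplicex:::.pairKey(pairs[, 1], pairs[, 2]))))
    }
})
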