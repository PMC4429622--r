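#' Simulation configuration
#'
#' Parameters of the synthetic exon-count generator. The defaults emulate
#' the kind of dataset the method targets: 60 samples (a well-powered bulk
#' RNA-seq cohort), genes with 4-10 union exons and two expressed isoforms
#' (most genes express only two isoforms at appreciable levels), negative
#' binomial gene totals around a baseline of 2000 counts with dispersion
#' 0.15, and planted modules whose genes share either a per-sample
#' expression factor (coexpression modules) or a per-sample splicing factor
#' driving isoform proportions (cosplicing modules) at strength 0.8.
#'
#' @param nSamples Number of samples.
#' @param nGenes Total number of genes.
#' @param exonsPerGene Integer range `c(min, max)` of exons per gene
#'   (min >= 2 so isoforms can differ).
#' @param nCoexprModules,nCospliceModules Number of planted modules of each
#'   type.
#' @param moduleSize Integer range `c(min, max)` of genes per module.
#' @param isoformsPerGene Number of isoforms (currently 2).
#' @param exprStrength,spliceStrength Factor strengths in `[0, 1]`.
#' @param dispersion Negative binomial dispersion of gene totals (0 gives
#'   deterministic totals).
#' @param baselineMean Baseline mean gene total per sample.
#' @param nMixedHubs Genes coupled to BOTH the first coexpression and the
#'   first cosplicing factor (produces mixed expression-splicing hubs).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `SimulationConfig` list.
#' @export
simConfig <- function(nSamples = 60L, nGenes = 200L,
                      exonsPerGene = c(4L, 10L),
                      nCoexprModules = 1L, nCospliceModules = 1L,
                      moduleSize = c(50L, 50L), isoformsPerGene = 2L,
                      exprStrength = 0.8, spliceStrength = 0.8,
                      dispersion = 0.15, baselineMean = 2000,
                      nMixedHubs = 0L, seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples),
                nGenes = as.integer(nGenes),
                exonsPerGene = as.integer(exonsPerGene),
                nCoexprModules = as.integer(nCoexprModules),
                nCospliceModules = as.integer(nCospliceModules),
                moduleSize = as.integer(moduleSize),
                isoformsPerGene = as.integer(isoformsPerGene),
                exprStrength = exprStrength,
                spliceStrength = spliceStrength,
                dispersion = dispersion, baselineMean = baselineMean,
                nMixedHubs = as.integer(nMixedHubs),
                seed = as.integer(seed))
    if (cfg$exprStrength < 0 || cfg$exprStrength > 1 ||
        cfg$spliceStrength < 0 || cfg$spliceStrength > 1)
        stop("strengths must lie in [0, 1]")
    if (cfg$exonsPerGene[1L] < 2L)
        stop("genes need at least 2 exons")
    if (cfg$isoformsPerGene != 2L)
        stop("only two isoforms per gene are supported")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate exon-level counts with planted co-expression/co-splicing modules
#'
#' Generates an exon x sample count table with known structure. For each
#' gene, two isoforms are defined as binary exon-inclusion vectors differing
#' in at least one exon. Per sample, the gene total `T` is drawn negative
#' binomial around the baseline; for genes in a coexpression module `T` is
#' multiplied by a shared per-sample lognormal factor (scaled by
#' `exprStrength`). The isoform proportion `theta` is a logistic transform
#' of a shared per-sample splicing factor for cosplicing-module genes
#' (scaled by `spliceStrength`) and of independent noise otherwise. Exon
#' means are `T` times the normalized inclusion mixture
#' `theta * iso1 + (1 - theta) * iso2`, and observed counts are Poisson
#' around the exon means, so gene totals match `T` in expectation.
#' Byte-identical output for the same seed.
#'
#' @param config A [simConfig()].
#' @return List with `counts` (an [ExonCounts]), and `truth`: a data.frame
#'   `genes` (`gene_id`, `module`, `type` in
#'   coexpression/cosplicing/mixed/background, and the latent `baseline`
#'   mean total), `isoforms` (list of 2 x p inclusion matrices) and
#'   `factors` (per-sample latent factor values).
#' @export
simulateExonCounts <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    nG <- config$nGenes
    nS <- config$nSamples
    .withSeed(config$seed, {
        ## module assignment (disjoint)
        sizes <- function(k) {
            if (k == 0L) return(integer(0))
            lo <- config$moduleSize[1L]
            hi <- config$moduleSize[2L]
            if (lo == hi) rep(lo, k)
            else lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
        }
        coexSizes <- sizes(config$nCoexprModules)
        cospSizes <- sizes(config$nCospliceModules)
        need <- sum(coexSizes) + sum(cospSizes) + config$nMixedHubs
        if (need > nG)
            stop("planted module sizes (", need, ") exceed nGenes (", nG,
                 ")")
        geneId <- sprintf("g%04d", seq_len(nG))
        type <- rep("background", nG)
        module <- rep("background", nG)
        pos <- 1L
        for (m in seq_along(coexSizes)) {
            idx <- pos:(pos + coexSizes[m] - 1L)
            type[idx] <- "coexpression"
            module[idx] <- paste0("coex", m)
            pos <- pos + coexSizes[m]
        }
        for (m in seq_along(cospSizes)) {
            idx <- pos:(pos + cospSizes[m] - 1L)
            type[idx] <- "cosplicing"
            module[idx] <- paste0("cosp", m)
            pos <- pos + cospSizes[m]
        }
        if (config$nMixedHubs > 0L) {
            idx <- pos:(pos + config$nMixedHubs - 1L)
            type[idx] <- "mixed"
            module[idx] <- "mixed"
        }
        ## gene structure
        p <- config$exonsPerGene[1L] +
            sample.int(config$exonsPerGene[2L] - config$exonsPerGene[1L] +
                       1L, nG, replace = TRUE) - 1L
        isoforms <- lapply(seq_len(nG), function(g) {
            iso1 <- rep(1, p[g])
            iso2 <- iso1
            nOff <- sample.int(p[g] - 1L, 1L)
            iso2[sample.int(p[g], nOff)] <- 0
            rbind(iso1 = iso1, iso2 = iso2)
        })
        baseline <- config$baselineMean * exp(stats::rnorm(nG, 0, 0.3))
        ## latent per-sample factors
        fExpr <- if (length(coexSizes))
            matrix(stats::rnorm(length(coexSizes) * nS),
                   nrow = length(coexSizes)) else
            matrix(0, 0, nS)
        gSplice <- if (length(cospSizes))
            matrix(stats::rnorm(length(cospSizes) * nS),
                   nrow = length(cospSizes)) else
            matrix(0, 0, nS)
        sE <- config$exprStrength
        sS <- config$spliceStrength
        sigmaE <- 0.6                 # lognormal sd of the expression factor
        cts <- vector("list", nG)
        for (g in seq_len(nG)) {
            ## gene total T per sample
            lf <- switch(type[g],
                coexpression = fExpr[as.integer(sub("coex", "", module[g])), ],
                mixed = if (nrow(fExpr)) fExpr[1L, ] else rep(0, nS),
                rep(0, nS))
            mu <- if (type[g] %in% c("coexpression", "mixed"))
                baseline[g] * exp(sE * sigmaE * lf -
                                  0.5 * (sE * sigmaE)^2)
            else baseline[g]
            tT <- if (config$dispersion < 1e-8) mu else
                stats::rnbinom(nS, mu = mu, size = 1 / config$dispersion)
            ## isoform proportion theta per sample
            eps <- stats::rnorm(nS)
            zf <- switch(type[g],
                cosplicing =
                    gSplice[as.integer(sub("cosp", "", module[g])), ],
                mixed = if (nrow(gSplice)) gSplice[1L, ] else rep(0, nS),
                rep(0, nS))
            z <- if (type[g] %in% c("cosplicing", "mixed"))
                sS * zf + sqrt(1 - sS^2) * eps else eps
            theta <- stats::plogis(2 * z)
            iso <- isoforms[[g]]
            w <- outer(iso["iso1", ], theta) +
                 outer(iso["iso2", ], 1 - theta)   # p x nS mixture weights
            w <- sweep(w, 2L, colSums(w), `/`)
            lambda <- sweep(w, 2L, tT, `*`)
            cts[[g]] <- matrix(stats::rpois(length(lambda), lambda),
                               nrow = p[g])
        }
        counts <- do.call(rbind, cts)
        colnames(counts) <- sprintf("s%02d", seq_len(nS))
        ec <- ExonCounts(counts,
                         geneId = rep(geneId, p),
                         exonId = unlist(lapply(p, function(k)
                             paste0("e", seq_len(k)))))
        list(counts = ec,
             truth = list(
                 genes = data.frame(gene_id = geneId, module = module,
                                    type = type, baseline = baseline),
                 isoforms = stats::setNames(isoforms, geneId),
                 factors = list(expression = fExpr, splicing = gSplice)))
    })
}

#' End-to-end planted-module recovery benchmark
#'
#' Simulates a dataset, runs the full pipeline (upper-quartile
#' normalization, low-count and low-connectivity filtering, per-gene
#' distances, network construction, TOM module detection) and scores how
#' well the detected modules recover the planted ones with the adjusted
#' Rand index (ARI), computed over the genes planted in modules of
#' `moduleType` (retained after filtering).
#'
#' @param config A [simConfig()] planting at least 2 modules overall.
#' @param flavor Network flavor to evaluate.
#' @param moduleType Which planted module type to score.
#' @param beta Soft-thresholding power.
#' @param minModuleSize,cutHeight Detector settings (see [detectModules()]).
#' @param filterThreshold Low-count filter threshold.
#' @return List with `ari`, `modules` (detected labels), `truth` (planted
#'   labels of the scored genes) and `n_scored`.
#' @export
recoveryBenchmark <- function(config,
                              flavor = c("cosplicing", "coexpression",
                                         "cosplicex"),
                              moduleType = c("cosplicing", "coexpression"),
                              beta = 6, minModuleSize = 30L,
                              cutHeight = 0.995, filterThreshold = 500) {
    flavor <- match.arg(flavor)
    moduleType <- match.arg(moduleType)
    if (config$nCoexprModules + config$nCospliceModules < 2L)
        stop("config must plant at least 2 modules")
    sim <- simulateExonCounts(config)
    norm <- upperQuartileNormalize(sim$counts)
    f1 <- filterLowCountGenes(norm$counts, threshold = filterThreshold)
    f2 <- filterLowConnectivityExons(f1$counts)
    ec <- f2$counts
    net <- if (flavor == "coexpression") {
        buildNetwork(ec, flavor = "coexpression", beta = beta)
    } else {
        metric <- if (flavor == "cosplicing") "cosine" else "canberra"
        buildNetwork(allGeneDistances(ec, metric = metric),
                     flavor = flavor, beta = beta)
    }
    modules <- detectModules(net, minModuleSize = minModuleSize,
                             cutHeight = cutHeight)
    truth <- sim$truth$genes
    scored <- truth$gene_id[truth$type == moduleType &
                            truth$gene_id %in% geneIds(net)]
    if (length(scored) < 2L)
        stop("fewer than 2 planted '", moduleType,
             "' genes survive filtering")
    ari <- .adjustedRand(truth$module[match(scored, truth$gene_id)],
                         modules[scored])
    list(ari = ari, modules = modules,
         truth = stats::setNames(truth$module[match(scored,
                                                    truth$gene_id)],
                                 scored),
         n_scored = length(scored))
}
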