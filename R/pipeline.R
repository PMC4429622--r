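#' Run the full cosplicing network pipeline
#'
#' Orchestrates normalization, filtering, per-gene distances, construction
#' of the three networks (coexpression, cosplicing, CoSplicEx), topology
#' statistics, module detection and quality, exclusive-hub selection and
#' cross-hub edge quartiles, and (when annotation tables are supplied) the
#' edge-factor shift tests. All artifacts are written to `outDir` as
#' TSV/JSON, together with a machine-readable copy of the resolved
#' configuration and the package version. All randomness flows from `seed`.
#'
#' @param input Path to an exon-count TSV (see [readExonCounts()]) or an
#'   [ExonCounts] object.
#' @param outDir Output directory (created if missing).
#' @param beta Soft-thresholding power (default 6).
#' @param filterThreshold Low-count filter threshold (default 500).
#' @param connectivityFilter Apply the bottom-quartile exon-connectivity
#'   filter (default TRUE).
#' @param minModuleSize,cutHeight Module detection knobs.
#' @param nPerm Permutations for module quality.
#' @param topQ,lowQ Hub selection quantiles (defaults: top 10%, bottom 80%).
#' @param edgeThreshold Minimum adjacency written to the edge lists.
#' @param annotations Optional [AnnotationBundle], or a named list of file
#'   paths (`ppi`, `tfbs`, `sfbs`, `mirna`, `domains`, `colocal`); missing
#'   components simply skip the corresponding analysis.
#' @param nBoot Bootstrap replicates for edge-factor CIs.
#' @param seed Integer seed.
#' @return The output directory, invisibly; the summary is in
#'   `summary.json`/`summary.md`.
#' @export
runPipeline <- function(input, outDir, beta = 6, filterThreshold = 500,
                        connectivityFilter = TRUE, minModuleSize = 30L,
                        cutHeight = 0.995, nPerm = 100L, topQ = 0.10,
                        lowQ = 0.80, edgeThreshold = 0,
                        annotations = NULL, nBoot = 1000L, seed = 1L) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(package_version =
                        as.character(utils::packageVersion("cosplicex")))

    ec <- stage("counts_io", {
        if (is.character(input)) readExonCounts(input) else input
    })
    cfg <- list(beta = beta, filter_threshold = filterThreshold,
                connectivity_filter = connectivityFilter,
                min_module_size = minModuleSize, cut_height = cutHeight,
                n_perm = nPerm, top_q = topQ, low_q = lowQ,
                edge_threshold = edgeThreshold, n_boot = nBoot,
                seed = seed,
                version = as.character(utils::packageVersion("cosplicex")))
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)

    norm <- stage("normalize", upperQuartileNormalize(ec))
    data.table::fwrite(norm$factors,
                       file.path(outDir, "normalization_factors.tsv"),
                       sep = "\t")

    filt <- stage("filter", {
        f1 <- filterLowCountGenes(norm$counts, threshold = filterThreshold)
        message("low-count filter removed ",
                f1$report$genes_removed_low_count, " of ",
                f1$report$genes_in, " genes")
        out <- f1
        if (connectivityFilter && nrow(f1$counts) >= 8L) {
            f2 <- filterLowConnectivityExons(f1$counts)
            message("exon-connectivity filter removed ",
                    f2$report$genes_removed_low_exon_connectivity,
                    " genes")
            out <- list(counts = f2$counts,
                        report = filterReport(
                            genesIn = f1$report$genes_in,
                            removedLowCount =
                                f1$report$genes_removed_low_count,
                            removedLowConnectivity =
                                f2$report$genes_removed_low_exon_connectivity))
        }
        out
    })
    jsonlite::write_json(filt$report,
                         file.path(outDir, "filter_report.json"),
                         auto_unbox = TRUE)
    writeExonCounts(filt$counts, file.path(outDir, "filtered_counts.tsv"))
    summary$filter <- filt$report

    nets <- stage("network", {
        dCan <- allGeneDistances(filt$counts, metric = "canberra")
        dCos <- allGeneDistances(filt$counts, metric = "cosine")
        list(coexpression = buildNetwork(filt$counts,
                                         flavor = "coexpression",
                                         beta = beta),
             cosplicing = buildNetwork(dCos, flavor = "cosplicing",
                                       beta = beta),
             cosplicex = buildNetwork(dCan, flavor = "cosplicex",
                                      beta = beta))
    })
    topo <- do.call(rbind, lapply(names(nets), function(f) {
        st <- topologyStats(nets[[f]])
        data.frame(flavor = f, n_genes = st$n_genes,
                   mean_k = mean(st$connectivity), density = st$density,
                   centralization = st$centralization,
                   heterogeneity = st$heterogeneity,
                   scale_free_r2 = st$scale_free_r2)
    }))
    data.table::fwrite(topo, file.path(outDir, "topology.tsv"), sep = "\t")
    for (f in names(nets))
        writeEdgeList(nets[[f]], file.path(outDir,
                                           paste0("edges_", f, ".tsv")),
                      threshold = edgeThreshold)
    summary$topology <- topo

    mods <- stage("modules", {
        lapply(nets, detectModules, minModuleSize = minModuleSize,
               cutHeight = cutHeight)
    })
    for (f in names(mods)) {
        writeModuleTable(mods[[f]],
                         file.path(outDir, paste0("modules_", f, ".tsv")))
        labs <- setdiff(unique(mods[[f]]), "unassigned")
        if (length(labs) > 0L) {
            q <- stage("module_quality",
                       moduleQuality(nets[[f]], mods[[f]], nPerm = nPerm,
                                     seed = seed))
            writeModuleTable(q, file.path(outDir,
                                          paste0("quality_", f, ".tsv")))
        }
    }
    summary$n_modules <- vapply(mods, function(m)
        length(setdiff(unique(m), "unassigned")), integer(1))

    hubs <- stage("hubs", {
        ks <- lapply(nets, connectivity)
        list(cosplicex = selectExclusiveHubs(ks$cosplicex,
                                             ks$coexpression,
                                             topQ = topQ, lowQ = lowQ),
             cosplicing = selectExclusiveHubs(ks$cosplicing,
                                              ks$coexpression,
                                              topQ = topQ, lowQ = lowQ),
             coexpression = selectExclusiveHubs(ks$coexpression,
                                                ks$cosplicex,
                                                topQ = topQ, lowQ = lowQ))
    })
    hubTab <- do.call(rbind, lapply(names(hubs), function(f)
        if (length(hubs[[f]]$genes))
            data.frame(network = f, gene_id = hubs[[f]]$genes)
        else NULL))
    if (!is.null(hubTab))
        data.table::fwrite(hubTab, file.path(outDir, "hubs.tsv"),
                           sep = "\t")
    summary$n_hubs <- vapply(hubs, function(h) length(h$genes), integer(1))
    if (length(hubs$coexpression$genes) && length(hubs$cosplicing$genes)) {
        a <- setdiff(hubs$coexpression$genes, hubs$cosplicing$genes)
        b <- setdiff(hubs$cosplicing$genes, hubs$coexpression$genes)
        if (length(a) && length(b)) {
            cq <- do.call(rbind, lapply(names(nets), function(f)
                data.frame(flavor = f,
                           t(crossHubEdgeQuartiles(nets[[f]], a, b)))))
            data.table::fwrite(cq, file.path(outDir,
                                             "cross_hub_quartiles.tsv"),
                               sep = "\t")
        }
    }

    if (!is.null(annotations)) {
        bundle <- stage("annotations", {
            if (is(annotations, "AnnotationBundle")) annotations
            else AnnotationBundle(
                ppi = if (!is.null(annotations$ppi))
                    readPpiPairs(annotations$ppi),
                tfbs = if (!is.null(annotations$tfbs))
                    readTfbsSets(annotations$tfbs),
                sfbs = if (!is.null(annotations$sfbs))
                    readSfbsVectors(annotations$sfbs),
                mirna = if (!is.null(annotations$mirna))
                    readMirnaSites(annotations$mirna),
                domains = if (!is.null(annotations$domains))
                    readDomainTable(annotations$domains),
                colocal = if (!is.null(annotations$colocal))
                    readColocalization(annotations$colocal))
        })
        shifts <- stage("edge_factors", {
            groups <- list()
            if (nrow(bundle@ppi))
                groups$ppi <- bundle@ppi
            if (length(bundle@tfbs))
                groups$tfbs <- tfbsSharedPairs(bundle)
            if (nrow(bundle@sfbs))
                groups$sfbs <- sfbsSharedPairs(bundle)$pairs
            if (length(bundle@mirna))
                groups$mirna <- sharedMirnaPairs(bundle)
            if (length(bundle@colocal))
                groups$colocal <- colocalPairs(bundle)
            rows <- list()
            for (fac in names(groups)) {
                if (nrow(groups[[fac]]) == 0L) {
                    message("no '", fac, "' pairs; skipped")
                    next
                }
                for (f in names(nets)) {
                    r <- tryCatch(
                        edgeWeightShift(nets[[f]], groups[[fac]],
                                        nBoot = nBoot, seed = seed,
                                        factorName = fac),
                        error = function(e) {
                            message("edge factor '", fac, "' skipped for ",
                                    f, ": ", conditionMessage(e))
                            NULL
                        })
                    if (!is.null(r))
                        rows[[length(rows) + 1L]] <-
                            as.data.frame(r[c("factor", "flavor", "shift",
                                              "ci_low", "ci_high",
                                              "p_value", "n_group",
                                              "n_background")])
                }
            }
            if (nrow(bundle@domains)) {
                for (f in names(nets)) {
                    r <- tryCatch(
                        domainMatchedComparison(nets[[f]], bundle,
                                                nBoot = nBoot, seed = seed),
                        error = function(e) {
                            message("domain comparison skipped for ", f,
                                    ": ", conditionMessage(e))
                            NULL
                        })
                    if (!is.null(r))
                        rows[[length(rows) + 1L]] <-
                            as.data.frame(r[c("factor", "flavor", "shift",
                                              "ci_low", "ci_high",
                                              "p_value", "n_group",
                                              "n_background")])
                }
            }
            if (length(rows)) do.call(rbind, rows) else NULL
        })
        if (!is.null(shifts)) {
            data.table::fwrite(shifts,
                               file.path(outDir, "edge_factors.tsv"),
                               sep = "\t")
            summary$edge_factors <- shifts
        }
    } else {
        message("no annotation tables supplied; edge-factor stage skipped")
    }

    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    md <- c("# cosplicex pipeline summary", "",
            paste0("- genes in: ", summary$filter$genes_in,
                   "; retained: ", summary$filter$genes_retained),
            paste0("- modules (coexpression/cosplicing/cosplicex): ",
                   paste(summary$n_modules, collapse = "/")),
            paste0("- exclusive hubs: ",
                   paste(names(summary$n_hubs), summary$n_hubs,
                         sep = "=", collapse = ", ")))
    writeLines(md, file.path(outDir, "summary.md"))
    invisible(outDir)
}
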