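# cosplicex

Weighted gene networks that see alternative splicing, not just expression.

Bulk RNA-seq resolves genes into exons, but classical weighted
coexpression analysis collapses each gene back to a single number per
sample before correlating genes. `cosplicex` keeps the exon resolution:
each gene is a vector of union-exon counts, each pair of samples gets a
distance under a metric sensitive to exon-inclusion changes, and two genes
are connected by the **Mantel correlation** of their sample-by-sample
distance matrices. The package is for transcriptomics researchers who want
to ask which genes coordinate their *splicing* — and which hub genes carry
that coordination — rather than (or in addition to) their expression
level.

## The method in brief

For gene *g* with exon counts `a_e,i` (exon *e*, sample *i*):

* Canberra distance `d(i,j) = Σ_e |a_ei − a_ej| / (a_ei + a_ej)` — each
  exon contributes in [0, 1]; sensitive to expression *and* splicing
  (the **CoSplicEx** network);
* cosine distance `d(i,j) = 1 − a_i·a_j / (‖a_i‖‖a_j‖)` — invariant to
  overall expression level; pure splicing signal (the **cosplicing**
  network).

The network edge between genes g and h is the Pearson correlation of the
`N(N−1)/2` lower-triangle entries of their two distance matrices (the
Mantel statistic), soft-thresholded as `a = |r|^β` with β = 6. A standard
coexpression network (Pearson correlation of exon-summed gene totals) is
built alongside. Downstream: scale-free topology fit, TOM module
detection, permutation module quality and cross-network preservation Z
scores, network-exclusive hub selection, Fisher gene-set enrichment, and
Hodges–Lehmann shift tests of edge strength for annotated gene-pair groups
(PPI, shared TFBS/SFBS/microRNA sites, chromosomal folding domains,
colocalization).

Pre-processing follows standard RNA-seq practice: upper-quartile
normalization, removal of genes under 500 mean counts, and removal of
genes whose exons all have bottom-quartile exon–exon correlation
connectivity.

## Worked example

Simulate a 60-sample dataset with two planted coexpression and two planted
cosplicing modules (50 genes each, strength 0.9), run the pre-processing,
and build the cosplicing (cosine) network:

```r
library(cosplicex)
sim  <- simulateExonCounts(simConfig(nGenes = 250, nCoexprModules = 2,
                                     nCospliceModules = 2,
                                     moduleSize = c(50, 50),
                                     exprStrength = 0.9,
                                     spliceStrength = 0.9, seed = 1))
norm <- upperQuartileNormalize(sim$counts)
ec   <- filterLowConnectivityExons(filterLowCountGenes(norm$counts)$counts)$counts
ec
#> ExonCounts: 228 genes, 1591 exons, 60 samples

net <- buildNetwork(allGeneDistances(ec, "cosine"), "cosplicing", beta = 6)
net
#> GeneNetwork 'cosplicing': 228 genes, beta = 6, mean connectivity = 0.8936

mods <- detectModules(net)
moduleSizes(mods)
#>         M1         M2 unassigned
#>         50         50        128
table(detected = mods[subset(sim$truth$genes, type == "cosplicing")$gene_id],
      planted  = subset(sim$truth$genes, type == "cosplicing")$module)
#>         planted
#> detected cosp1 cosp2
#>       M1    50     0
#>       M2     0    50
```

The cosine network recovers exactly the two planted cosplicing modules —
and, because the cosine distance ignores expression level, it leaves the
two coexpression modules unassigned (the Pearson network recovers those
instead). Hub enrichment uses the exact hypergeometric test; for example,
an overlap of 65 genes between 425 network-exclusive hubs and 660
disease-candidate genes in a 9066-gene universe gives

```r
enr <- fisherEnrichment(425, 660, 9066, overlap = 65)
signif(enr$p_one_sided, 3)   # 5.14e-09
round(enr$odds_ratio, 2)     # 2.44
```

— about twice as many hub candidates as expected by chance.

`runPipeline("counts.tsv", "out/", seed = 1)` orchestrates everything and
writes TSV/JSON artifacts; `inst/scripts/cosplicex.R` wraps `simulate`,
`network` and `run` as shell subcommands. See the methods vignette
(`vignettes/cosplicing-networks.Rmd`) for the model, conventions and
design choices.

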