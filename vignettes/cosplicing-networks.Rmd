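---
title: "Inferring gene cosplicing networks from exon-level counts"
author: "cosplicex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene cosplicing networks from exon-level counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosplicex)
```

## The problem and the model

Weighted gene coexpression analysis summarizes every gene as one number per
sample (its expression level) and connects genes whose levels covary. That
summary discards the exon-level resolution of RNA-seq: a gene is a mixture
of isoforms, and samples can differ in *which* exons are included even when
the total output is constant. `cosplicex` infers networks from that
isoform-level signal.

Each gene is represented as its vector of union-exon counts
\(a = (a_1, \dots, a_p)\) per sample. For every gene we compute the
\(N \times N\) matrix of distances between all sample pairs:

* **Canberra** (the *CoSplicEx* network):
  \(d(i,j) = \sum_e |a_{ei} - a_{ej}| / (a_{ei} + a_{ej})\).
  Each exon contributes a value in \([0, 1]\), so \(d \in [0, p]\). The
  metric responds to overall expression changes *and* exon-inclusion
  changes.
* **cosine** (the *cosplicing* network):
  \(d(i,j) = 1 - a_i \cdot a_j / (\|a_i\| \|a_j\|)\). Scaling a sample's
  whole exon vector leaves the distance unchanged, so this metric sees only
  relative exon usage — pure splicing signal.

Two genes are connected when their distance matrices agree across sample
pairs: the edge statistic is the **Mantel correlation**, the Pearson
correlation of the \(N(N-1)/2\) lower-triangle entries of the two
matrices. Edges are soft-thresholded into an adjacency
\(a_{ij} = |r_{ij}|^\beta\) with \(\beta = 6\) by default, exactly as in
weighted coexpression analysis, and the usual topology statistics
(connectivity, density, centralization, heterogeneity, scale-free fit),
TOM-based module detection, permutation module quality/preservation Z
scores, hub selection and edge-factor tests are computed on top. A
classical coexpression network (Pearson correlation of exon-summed gene
totals) is built alongside for comparison.

Assumptions worth stating: counts are non-negative and exon order within a
gene is fixed; samples are exchangeable replicates of one condition (the
Mantel correlation has no notion of covariates); genes behave
predominantly as mixtures of two expressed isoforms, which is what the
synthetic generator emulates.

## Pre-processing

`upperQuartileNormalize()` scales each sample by its upper-quartile factor:
the 75th percentile of nonzero gene totals divided by the library size,
with factors normalized to geometric mean 1; counts are divided by
`library size x factor` and multiplied by the mean library size. One
property deserves a note: the factor `uq/libsize` is a *scale-free*
functional of a sample's count distribution, so re-normalizing an already
normalized table reproduces the same factors rather than factors of 1 —
the transformation is a fixed point only up to one global constant, and the
post-normalization upper quartiles are exactly equal across samples. The
tests assert exactly that property.

Two filters then remove noise-dominated genes. `filterLowCountGenes()`
drops genes whose mean (over samples) exon-summed total is strictly below
500 — the inequality is strict at the boundary, and the default pipeline
applies the filter *after* normalization (both choices are exposed).
`filterLowConnectivityExons()` computes every exon's connectivity (row sum
of absolute Pearson correlations to all other exons, in memory-bounded
blocks that reproduce the dense result exactly) and removes a gene only
when *all* of its exons fall strictly below the 25th-percentile cutoff.
Zero-variance exons get correlation 0 by convention, with a warning,
rather than an error.

## Numerical conventions

* Canberra terms with \(0/0\) contribute 0. Cosine distance of two all-zero
  vectors is 0; of exactly one all-zero vector, 1 (filtering normally
  removes such genes first).
* The full Mantel matrix uses a fast path — each gene's lower triangle is
  centered and L2-normalized so the matrix of correlations is a single
  crossproduct — asserted to match the pairwise loop within 1e-10.
  Genes with constant distance matrices get correlation 0 with a warning.
* The adjacency is unsigned, \(|r|^\beta\): with the even default
  \(\beta = 6\) the absolute value changes nothing, and odd powers stay
  valid.
* The scale-free fit is the \(R^2\) of `log10(frequency)` on
  `log10(mean k)` over 10 equal-width connectivity bins, empty bins
  dropped.
* Hub selection uses empirical quantiles with linear interpolation and
  inclusive boundaries (ties kept). Cross-hub edge quartiles use an
  inclusive-upper convention, so an all-equal network puts every edge in
  the top quartile.

## Module detection and the cut height

Modules are detected by average-linkage clustering on `1 - TOM` with a
static cut and a minimum size of 30; small clusters become `"unassigned"`
and labels are size-ranked (`M1`, `M2`, ...), with a color-name mapping
available via `moduleColorMap()` for familiarity. The cut height default
is 0.995: at \(\beta = 6\), a coherent module whose within-module
correlations sit around 0.4 produces TOM dissimilarities — and
average-linkage merge heights — between 0.99 and 1, while unrelated genes
merge essentially at 1. A cut at 0.99 keeps only the very strongest
modules; 0.995 retains modules at realistic strengths without admitting
spurious clusters in strength-0 data (the recovery tests assert both
directions). Both knobs are arguments everywhere they matter.

Module quality and preservation are permutation Z scores: observed
within-module density, a connectivity statistic (for preservation, the
mean of `cor.kIM` and `cor.adj` between reference and test network), and
separability, each standardized against random same-size gene sets drawn
from the *sorted* gene ids so that results are invariant to gene order
given the seed. `Z_summary` is the mean of the density and connectivity
Zs. When a null is degenerate — e.g. comparing a network with itself makes
every connectivity correlation exactly 1, so the null has zero variance —
that component is undefined (0/0) and is reported `NA` and excluded from
`Z_summary` rather than coerced to a number. Z below 2 is read as poor,
above 10 as high quality/preservation.

## Edge factors

Shifts in edge strength for annotated gene-pair groups (PPI partners,
pairs with TFBS Jaccard overlap strictly above 0.5, pairs with similar
length-21 SFBS multiplicity vectors, pairs sharing at least two microRNA
sites, same-folding-domain pairs, spatially colocalized pairs) are
measured on the **correlation scale** by default — shifts of 0.03–0.14 are
meaningful there, and would be invisible after raising to the 6th power.
The estimate is the Hodges–Lehmann shift (median of all pairwise
group-minus-background differences) with a 95% percentile bootstrap CI
over pair resampling (the bootstrap construction is our choice; group
sizes here make the percentile method adequate) and a two-sided
Mann–Whitney p-value. The random background draws gene pairs uniformly
without replacement, excluding the group pairs, at 10x the group size by
default. The SFBS "shared" threshold defaults to the empirical lower
quartile of all pair distances; the value 7.6 seen on mouse striatum data
is dataset-specific and deliberately not hard-coded. The domain analysis
compares same-domain pairs against cross-domain pairs on the same
chromosome matched greedily on midpoint separation within a relative
tolerance of 0.2, each control used once; matching depends only on
distances, so it is invariant to gene-id relabeling.

## What the synthetic generator emulates — and what it does not

`simulateExonCounts()` plants known structure so every stage is testable
without downloads. Per gene: two isoforms as binary exon-inclusion vectors
differing in at least one exon; a per-sample gene total \(T\) drawn
negative binomial (dispersion 0.15) around a lognormal per-gene baseline
(sd 0.3) of 2000 counts; for coexpression-module genes, \(T\) is
multiplied by a shared per-sample lognormal factor (sd 0.6, mean-corrected
so totals stay unbiased); the isoform proportion \(\theta\) is a logistic
transform (slope 2) of a shared per-sample splicing factor for
cosplicing-module genes, mixed with independent noise as
\(s \cdot g + \sqrt{1 - s^2}\,\epsilon\) so the variance of \(\theta\) does
not change with the strength \(s\). Exon means are \(T\) times the
normalized inclusion mixture (so gene totals match \(T\) in expectation),
and observed counts are Poisson. Defaults: 60 samples, 200 genes, 4–10
exons per gene, one 50-gene module of each type, strength 0.8 —
moderately strong coordination of the kind a well-powered bulk cohort can
resolve.

The generator does *not* emulate positional or GC bias, more than two
isoforms, correlated module memberships, batch structure, or read-level
noise. Passing the recovery and calibration tests therefore shows the
statistics behave as designed under the stated data model — not that any
particular biological dataset will yield modules at these strengths.

Problem sizes used by the test-suite and the acceptance script — 250-gene
networks, 60 samples, 200 permutations, 400–1000 bootstrap replicates, 20
to 50 seeded repeats — were chosen as the smallest sizes at which the
planted effects and their nulls are clearly separated.

## Design choices on open points

* "Average counts" for the low-count filter is read as the mean over
  samples of the union-exon gene total; both strict inequalities follow
  the stated thresholds ("less than 500", bottom quartile).
* Whether filtering and exon connectivity use raw or normalized counts is
  configurable; the defaults apply both after normalization.
* The coexpression network uses the exon-summed gene total as the
  per-gene summary.
* The Mantel flavors never compute permutation p-values — edges are
  weights, not tests.
* `scaleFreeConvergence()` accepts \(\beta = 0\) (all-ones adjacency,
  density 1) as a degenerate anchor of the convergence curve, while
  `buildNetwork()` requires \(\beta > 0\).
* Enrichment of hub sets reports both one- and two-sided Fisher p-values;
  where a set is *depleted* rather than enriched the two numbers tell
  different stories, and the package does not adjudicate.

## Known limitations

The dense gene x triangle matrix makes the Mantel fast path memory-bound
around a few thousand genes times a few hundred samples (chunked products
bound the gene dimension only). Module detection uses a static tree cut,
not dynamic hybrid cutting. Preservation statistics implement the
documented density/connectivity/separability categories, not the full
battery of preservation statistics found elsewhere; numbers are comparable
in spirit, not digit-for-digit. The CLI wrapper covers simulation, single
networks and the full pipeline; per-stage shell subcommands are left to
the exported functions.

## A minimal run

```{r example, eval = FALSE}
sim <- simulateExonCounts(simConfig(seed = 7))
norm <- upperQuartileNormalize(sim$counts)
ec <- filterLowConnectivityExons(filterLowCountGenes(norm$counts)$counts)$counts
net <- buildNetwork(allGeneDistances(ec, "cosine"), "cosplicing", beta = 6)
detectModules(net)
```

or, end to end with artifacts on disk:

```{r pipeline, eval = FALSE}
runPipeline("counts.tsv", "results/", seed = 1)
```
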