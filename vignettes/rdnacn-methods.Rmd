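---
title: "Methods: rDNA copy number and variation from read depth"
author: "rdnacn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rDNA copy number and variation from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnacn)
```

## The estimation problem

The 45S ribosomal DNA is a tandem repeat of a ~43 kb unit carrying
the 18S, 5.8S and 28S rRNA genes, their transcribed spacers (5'ETS,
ITS1, ITS2, 3'ETS) and a large non-transcribed intergenic spacer
(IGS).  About 31% of the canonical human unit is transcribed.
Because the repeats are collapsed onto a single consensus in any
reference-based analysis, copy number must be inferred from relative
read depth rather than called directly.

`rdnacn` uses the coverage-ratio estimator.  For a sample with mean
per-base depth $\bar d_r$ over coding region $r$ and background
coverage $B$ (the median of per-exon mean depths over a catalog of
single-copy exons), the copy number is

$$\widehat{CN}_r = \phi \cdot \frac{\bar d_r}{B},$$

with ploidy factor $\phi = 2$ by default: one background unit of
coverage corresponds to the two copies a single-copy exon contributes
to a diploid genome.  The reported magnitudes (hundreds of copies)
and ddPCR assays against two-copy autosomal reference genes both rely
on this convention; $\phi$ is an argument for other ploidies.

Assumptions: depth is proportional to template copy number with a
sample-specific proportionality constant that cancels in the ratio
(the estimator is exactly invariant to rescaling all depths); the
exon catalog is genuinely single-copy (the admission rule keeps one
exon of at least 300 bp per gene); no GC or mappability correction is
applied.  Using the median for $B$ makes the background robust to a
minority of exons with copy-number changes of their own.

## Paired comparisons and cohort tests

For matched pairs, $\Delta CN_r = \widehat{CN}_r(\text{tumor}) -
\widehat{CN}_r(\text{normal})$ removes the individual's germline copy
number.  Project-level loss is assessed with a two-sided one-sample
t test of the per-pair $\Delta$'s against 0 — equivalent to a paired
t test — because the per-pair differencing already handles the
pairing; a Wilcoxon signed-rank alternative is available
(`method = "wilcoxon"`) for heavy-tailed cohorts.  Degenerate inputs
are given fixed conventions: all differences zero gives statistic 0
and p = 1; zero variance around a nonzero mean is reported as p = 0
with a `degenerate` flag rather than NaN.

A project is flagged as loss-significant in `run_cohort()` when the
configured region's test (default 18S) has p below `alpha` (default
0.05) with a negative mean delta.

## Exon covariation

The normalized exon copy numbers used for the background double as a
genome-wide scan: each exon's values form a samples × exons matrix on
the same copies-per-diploid-genome scale.  Per exon and project, a
paired t test of tumor vs normal is computed in closed form from the
per-pair differences (verified against `stats::t.test` in the test
suite), and Benjamini–Hochberg q values are computed within each
project's family of exons.  `bh_fdr()` delegates to
`stats::p.adjust(method = "BH")`; the test suite checks it against a
brute-force implementation of the step-up definition.

Selection over a designated project group supports two rules.  With
`mode = "any"` an exon needs q ≤ 0.05 in at least one group project;
with `mode = "all"` it must reach the threshold in every group
project.  The pipeline uses `"all"` when asking which exons co-vary
with the loss-positive group: a union over three projects of 16,000
tests each otherwise accumulates on the order of fifty per-project
false discoveries, which would contaminate the clustering input,
whereas an exon genuinely tracking the group signal is expected to
show it in each member project.

Significant exons are clustered on their per-project mean deltas
(Euclidean distance, average linkage, `cutree` at k = 4 by default;
all configurable).  The dendrogram cut is a display/selection device,
not an inference, so the gain cluster is defined operationally: the
anchor is the cluster whose profile is most positive in the positive
projects and nearest zero in the negative projects (score =
positive-project mean − |negative-project mean|), and the gain set
additionally includes any cluster whose profile lies closer to the
anchor than to the all-zero profile.  The inclusion rule matters when
the selected set is homogeneous: a fixed-k cut then shards one tight
gain block into sub-clusters, and without re-unification a singleton
shard can win the score by noise alone.  Rows are sorted by exon id
before clustering so results are order-independent, and ties resolve
lexicographically.

Term enrichment is a plain upper-tail hypergeometric test per term
against a user-supplied gene→term table over the exon-derived gene
universe — no ontology graph propagation and no multiplicity
adjustment of the per-term p values, which are reported raw.

## Repeat SNVs and allele numbers

Each pileup column carries A/C/G/T read counts and a representative
phred quality.  The predominant (majority) base is compared to the
consensus; ties that include the reference resolve to the reference
(a conservative no-call), ties between two alternatives resolve
alphabetically.  A mismatch passes when quality is strictly greater
than 20 and depth is at least 10 (the depth floor is this package's
choice; quality-20 records are excluded by the strict inequality).

Across a pair, a position is *shared* when both genomes carry a
passing SNV with the same alternative base; otherwise it is *unique*
to the genome carrying it, and a position with different alternative
bases in the two genomes is unique in both.  Densities are SNVs per
kb per annotated region; hotspot summaries count, per position, the
genomes carrying a unique SNV there.

At shared positions, the allele number (1–4) counts bases with at
least `min_reads = 5` reads and `min_fraction = 0.1` of the depth —
the support rule is exposed because only "evidence of 1–4
nucleotides" is inherent to the statistic, not a specific rule.  The
per-genome mean over shared positions gives $\bar A$, and
$\Delta\bar A = \bar A_{tumor} - \bar A_{normal}$ is tested against 0
per project with the same one-sample t machinery.  Indels are outside
scope.

## ddPCR quantitation

A droplet assay partitions the reaction into ~20,000 droplets; with
$p$ the positive fraction, the per-droplet concentration is the
Poisson correction $\lambda = -\ln(1 - p)$, and copy number per
genome is $2\,\lambda_{target}/\lambda_{reference}$ for a two-copy
reference gene.  Droplet volume cancels in the ratio and is kept
(QX200 nominal 0.85 nL) only for optional absolute concentrations.
Saturated channels (every droplet positive) are errors, not
estimates.  A delta-method 95% interval on the log-ratio is reported
per assay.  Replicate summaries use the n−1 SD and CV = SD/mean.

## Nucleolar morphometry

The operator chain is: maximum-intensity projection; rolling-ball
background subtraction with radius 5; Gaussian blur with σ = 2 px;
binary mask at 0.25 × the maximum processed intensity; 8-connected
component labeling; per-region pixel areas.  Two numerical choices
deserve note.

First, the rolling ball is implemented in the apex formulation: the
background at each pixel is the apex height of a sphere of the given
radius rolled beneath the intensity landscape, computed as a
grayscale erosion with the spherical structuring function plus the
radius.  The alternative — a full morphological opening with a flat
disc — erases any smooth blob wider than the disc, which would make
nucleoli of realistic size unmeasurable at radius 5; the apex
formulation leaves a residual whose footprint tracks the blob, and
the relative threshold then recovers the region.  Second, because a
spherical structuring element mixes intensity and pixel units,
intensities are first normalized to an 8-bit-equivalent range
(max = 255).  Fluorescence units are arbitrary, so this loses
nothing, and it makes the whole segmentation exactly invariant to
rescaling the input intensities — multiplying an image by any
positive constant changes no region assignment.

Morphological erosion is computed by running `pmin` over shifted
copies of the image (pixels outside the frame are ignored), and
labeling merges the diagonal adjacencies of a 4-connected pass into
8-connected components, matching the particle-analysis convention of
common image software.  An all-zero image yields an empty region
table, not an error.  No minimum-area filter is applied by default
(`min_area = 0`).

## The synthetic cohort generator

The generator emulates the study design the analysis targets: eight
genome projects of matched tumor–normal pairs with the realized
cohort sizes 19, 36, 16, 40, 12, 12, 14 and 13 pairs (162 pairs in
all), three of which carry a planted rDNA loss.  Defaults: germline
copy number drawn per pair from N(400, 50²) copies per diploid
genome; planted loss 80 copies (inside the ~70–90 band the loss
signal is expected to occupy); a 16,022-exon single-copy catalog with
lengths 300–2,000 bp; a planted 100-exon gain cluster (+1 copy in
positive-project tumors only); mean coverage 30 per two copies;
negative-binomial per-base counts with overdispersion 0.1 (variance
μ + 0.1μ², Poisson when 0); sequencing error rate 0.1%.  Coverage is
simulated at the count level — per-base over the repeat unit, and
per-exon means drawn as averages of per-base counts in closed form —
because alignment is upstream of the package's boundary; ingest
contracts assume deduplicated, concordantly mapped coverage.

Pileups plant SNVs at configured allele fractions with column quality
30; error-carrying columns get quality 15 (10% at 25) so that error
noise straddles the >20 filter.  Shared-SNV allele structure is
planted by giving a configurable fraction of tumor columns residual
reference evidence (alt fraction 0.7), so the expected
$\Delta\bar A$ equals the planting probability.  Nucleolus images
render each disk as a spherical-cap intensity profile falling to
zero at the radius edge — the smooth-blob shape of fluorescent
staining; a flat-top disk is exactly the degenerate case rolling-ball
background estimation cannot handle and does not occur in real
images — while the truth area remains the exact count of pixel
centers within the radius.  Every generator is a pure function of
its configuration and seed, with the caller's RNG state restored.

What the generator does not emulate, and what green tests therefore
do not show about real data: mapping bias and multi-mapping within
the repeat, GC and insert-size effects on depth, subclonal copy
number and tumor purity, aneuploidy beyond planted whole-chromosome
changes, correlated (non-independent) errors in pileups, and optical
artifacts in images.

## Problem sizes and numerical conventions

The test suite and the acceptance script use scaled-down units for
speed, chosen once as adequate for the statistical question asked:
copy-number recovery uses a 4.3 kb scaled unit (region proportions
preserved), 1,000 exons, 30× depth, 50 replicate seeds; loss
detection uses 20 pairs, with null calibration over 1,000
reduced-size cohorts (5 pairs, 100 exons, 1 kb unit, 10×); cluster
recovery uses the full 16,000-exon, 162-pair design; allele recovery
uses 50 pairs with 20 shared SNVs each.  Medians of even-length
vectors use the midpoint convention (the background feeds a
division).  All cohort randomness flows from one seed via fixed
per-stage offsets, so identical configurations reproduce identical
outputs.

## Limitations

The estimator reports relative copy number against the exon-catalog
background and inherits any bias shared by the whole catalog.  The
allele-number statistic is bounded (1–4) and its support rule is a
stated convention, not an inference.  Enrichment results depend
entirely on the supplied annotation table.  The imaging chain
measures areas of distinct spots; touching nucleoli merge into one
region, and no per-cell assignment is attempted.  BAM/SAM ingest is
not provided: the package consumes coverage and pileup tables
produced by an upstream alignment workflow.
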