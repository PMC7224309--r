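---
title: "Quantifying loss of tissue identity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loss of tissue identity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(identiscape)
```

# Overview

Severe cellular stress — endoplasmic reticulum stress in hepatocytes being
the motivating case — does more than switch on a stress program: it
transiently represses the gene battery that defines what the cell *is*.
`identiscape` implements the computational pipeline needed to quantify that
loss of molecular identity from standard epigenomic and transcriptomic
inputs:

1. **Identity-gene calling** from broad H3K4me3 domains across tissues.
2. **Differential H3K27ac region classification** from bin-level statistics.
3. **Super-enhancer identification** by signal rank ordering.
4. **TF co-binding stratification** of enhancer inactivation and
   cistrome-overlap enrichment.
5. **Expression statistics of identity loss**: globally scaled fold
   changes, bagplots, repression-quartile enrichment, gene-set enrichment
   scores, and single-cell gene-set projection.
6. **Projection of perturbed transcriptomes onto a developmental axis.**

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the whole pipeline runs and is tested
without any external download.

# Coordinate conventions

All regions are BED-convention 0-based half-open intervals `[start, end)`;
a TSS at position `p` belongs to a region iff `start <= p < end`. Overlap
means sharing at least one base on the same chromosome (exact string match,
no `"chr"` aliasing); strand is carried in TSS tables but ignored by
overlap tests. Internally, interval algebra is delegated to
`GenomicRanges`/`IRanges` with a 1-based-closed conversion at the boundary,
which preserves these semantics exactly.

# Identity genes from broad H3K4me3 domains

Within each tissue, a peak is a **broad domain** when its length strictly
exceeds `broad_multiplier` (default 3) times the median peak length of that
tissue; the median of an even count is the mean of the two central values.
The focal tissue's broad domains are then compared against the *broad
domains* (not raw peaks) of every other tissue: the shared fraction is the
fraction of other tissues with at least one base of overlap, and a domain
is tissue-specific (**ID**) when that fraction is strictly below
`specificity_threshold` (default 0.25), otherwise ubiquitous (**UBQ**).
Both cutoffs are strict by design ("more than" three times, "less than" a
quarter of tissues).

Genes are classified through their TSS: **ID** if any TSS falls in an ID
domain, else **UBQ** if any falls in a UBQ domain, else **OTHER**. ID takes
precedence when a gene touches both domain types, because identity genes
are the analysis target and the output classes must partition the
annotation. "Detected in another tissue" is operationalized as ≥ 1 bp
overlap; a minimum reciprocal-fraction rule would also be defensible, and
the threshold is exposed in `identity_config()` rather than hard-coded.

The tissue-specificity expression index of a gene is the mean of its
focal-tissue replicates minus the mean over control tissues of per-tissue
replicate means — a two-stage average, so unbalanced replicate counts do
not overweight any tissue.

# Differential H3K27ac regions

The differential engine that produces per-bin log2 fold changes and
p-values (a quasi-likelihood count model in typical workflows) is upstream
of this package; `identiscape` consumes its bin table. Bin p-values are
Benjamini–Hochberg adjusted **genome-wide** (one FDR filter over all tested
bins, not per peak). A bin is UP when `fdr <= 0.05` with positive log2
fold change, DOWN when negative; a significant bin with fold change exactly
0 has no sign and is NS.

Bins attach to pre-merged peaks when they overlap by at least
`min_bin_peak_overlap` (default 75 bp); a bin clearing the threshold for
several peaks goes to the largest overlap (ties to the leftmost peak).
Within a peak, with `u` UP and `d` DOWN bins, the merged region is UP when
`u/d >= 2`, DOWN when `u/d <= 0.5`, UNCHANGED when no significant bins
exist, and **MIXED** in between — the middle band is unnamed in typical
analyses, and MIXED regions are excluded from UP/DOWN gene sets. The
zero-denominator cases follow the natural limits: only-UP bins give UP,
only-DOWN give DOWN. Genes link to regions by direct TSS overlap or
through a user-supplied precomputed distal link table (distal
enhancer–gene linking itself is out of scope).

One property worth stating plainly: because the BH filter is genome-wide,
the presence of strong true signal raises the rejection threshold for all
bins, so a small fraction of truly null peaks will receive a direction
call in mixed data. This is inherent to a single global FDR filter; the
package's calibration guarantee is therefore formulated under the
complete null, where the UP+DOWN region rate stays within 1.5x the nominal
FDR, and power is ≥ 90% correct-direction recovery for planted regions at
effect size 1 (ten 150-bp bins per region, bin noise SD 0.4).

# Super-enhancers by rank ordering

Constituent peaks are stitched when separated by at most `stitch_distance`
(default 12,500 bp; TSS exclusion distance 0, i.e. no promoter masking),
and each stitched enhancer's signal is the sum of its member peak scores.
Enhancers are sorted by ascending signal; rank and signal are both min–max
scaled to `[0, 1]`, and the cutoff is the signal at the first point (from
the low end) whose forward finite-difference slope reaches 1 — the
discrete version of the geometric tangent rule, with no curve smoothing.
An enhancer is *super* iff its signal strictly exceeds the cutoff signal,
so ties at the cutoff are excluded and the flags are invariant under
positive affine rescaling of all signals. All-equal signals yield zero
super-enhancers by convention. Scaling uses the maximum; some
implementations scale by a high quantile instead, which would be a
one-line change but is not the default here. A slope tolerance of 1e-9
handles curves whose slopes sit numerically on 1 (e.g. exactly linear
signal). Identity domains are then split into ID+SE / ID−SE by ≥ 1 bp
overlap with any super-enhancer, and genes inherit the split through
their TSS.

# TF co-binding and enrichment

The occupancy matrix is binary enhancer × TF overlap. For the
stratification of enhancer inactivation, enhancers are first split by
focal-TF binding and then by the count of *additional* bound TFs into
closed integer strata (default 0–2, 3–5, 6–8, which must tile
`0..nTF-1`; out-of-range counts are an error rather than silently
clipped). Cell values are percentages of the stratum overlapping any DOWN
region; an empty stratum reports `NA`, never 0.

Cistrome enrichment uses a 2×2 table per target set over a region
universe — by default all tested regions (UP, DOWN and unchanged
together), mirroring the UP / DOWN / ALL comparison; the universe is an
explicit argument because published locus-overlap analyses do not always
state theirs. The p-value is always Fisher's exact test on the raw table;
the log-odds adds 0.5 to every cell only when a zero cell exists (Haldane
correction), keeping zero-overlap sets finite. A query equal to the whole
universe offers no contrast and reports log-odds 0. Enrichment matrices
are clustered with Euclidean distance and Ward linkage on squared
distances (`ward.D2`), the standard pairing for log-odds heatmaps.

# Expression statistics

**Size factors** use the median-of-ratios rule: per sample, the median
over genes (with positive geometric mean) of the count divided by the
gene's geometric mean. This is the arithmetic median of ratios; the
common implementation exponentiates the median of log ratios, which
coincides except for even counts of usable genes, where the two central
values are averaged on different scales.

**Scaled fold changes.** To make fold changes comparable across datasets,
each dataset is processed alone: the lowest-expressed `drop_fraction`
(default 20%) of genes by baseline mean is discarded
(`floor(drop_fraction * n)` genes, ties broken by gene id), the whole
retained matrix is z-scaled by its *global* mean and *global* SD over all
values of all conditions, and the per-gene scaled fold change is the mean
scaled perturbed value minus the mean scaled baseline value. The scaled
fold change is a positive multiple of the raw one within a dataset
(Spearman correlation 1), but lives on a scale comparable across studies.

**Bagplots.** The bivariate boxplot uses exact Tukey (halfspace) depth:
for each point, the angles to all other points are sorted and an open
semicircle is swept to find the fullest one, giving the minimal closed
halfplane count in `O(n log n)` per point. Exact computation is used up to
n = 5,000; beyond that, 1,000 random projection directions (fixed internal
seed) give an upper-bounding approximation. The depth median is the
deepest point (centroid of the deepest set on ties); the bag is the convex
hull of the `ceiling(n/2)` deepest points, with ties at the depth cut
broken by distance to the depth median and then by index, so the bag
membership count is exact by construction; the loop inflates the bag by a
factor of 3 about the depth median (the classical default), and points
outside the loop are outliers. Collinear input is rejected with advice to
use a univariate summary.

**Repression quartiles.** Repressed genes (scaled fold change < 0 by
default — no significance gate, configurable) are ranked by increasing
repression and split into four near-equal quartiles, remainder genes going
to the earlier quartiles (7 genes split 2/2/2/1). Identity-gene fractions
are reported relative to Q1 (set to 1); when Q1 has no identity genes the
absolute fractions are returned with a flag instead of undefined ratios.
Per-quartile chi-square tests against Q1 are BH-corrected. Whether
ranking uses raw or scaled fold changes is a caller choice; the function
takes whatever fold-change column the table provides (`scaled_fc`).

**Gene-set enrichment.** The running sum increments by
`|score|^weight / sum` at set members and decrements by `1/(N-m)` at
non-members; the enrichment score is the signed extremum, `weight = 1`
being the "weighted" statistic and `weight = 0` the classic
Kolmogorov–Smirnov form. The ranking metric ("difference of classes") is
supplied by the caller, with `rank_by_class_difference()` as the provided
helper; normalization and FDR come from gene-set permutations (default
1,000, seeded): NES divides by the mean absolute same-sign permuted score,
and the FDR is the fraction of same-sign normalized permutation scores at
least as extreme. A set covering the whole list is rejected (`m = N`
makes the statistic degenerate).

**Single-cell projection** is deliberately simple: normalize counts by
size factors, then report the per-cell mean of the set genes.

# Developmental projection

Injury studies are pooled with a developmental reference. Batch
correction is **location-only and anchor-referenced**: per gene, each
non-reference batch is shifted by a constant so that the mean of its
anchor-condition samples (non-injured controls) equals the reference
batch's anchor-stage (adult) mean; the reference batch is untouched. Full
empirical-Bayes batch correction in mean-only mode is not reimplemented;
an optional normal-prior shrinkage of per-gene shifts toward the
batch-wide mean shift (method-of-moments hyperparameters) is available but
off by default, and the plain-mean adjustment is the documented,
deterministic default.

The axis itself is the first principal component of the reference-batch
samples only, in covariance form (genes centered by reference means, no
unit-variance scaling), computed from the samples × samples cross-product
so gene count does not inflate the eigenproblem. All other samples are
*supplementary individuals*: centered with the reference gene means and
projected onto the unit-norm loading vector. The sign is fixed so adult
reference samples average positive, making "more mature" unambiguously
rightward. The variance fraction is the leading eigenvalue over the
trace. Genes are intersected across studies before everything; prenatal
stages may be included in the fit and simply dropped from display by the
caller.

# The synthetic-data generator

Every generator is a pure function of `synth_config()` — identical seeds
give byte-identical output, and the internal RNG state is isolated from
the caller's. The defaults define the study conditions used throughout
the tests and the acceptance script:

* **Peaks** (`gen_tissue_peaks`): 10 tissues, 2,000 genes with TSS 20 kb
  apart on one chromosome, 1,000 background peaks per tissue with
  lognormal lengths (median 500 bp, log-SD 0.3), 200 identity genes with a
  2,500-bp domain planted over their TSS in the focal tissue only, and 200
  ubiquitous genes with the same domain planted in *every* tissue. The
  planted length (5× the background median) clears the 3×-median breadth
  rule with margin while background outliers remain rare.
* **Bins** (`gen_bins`): 1,000 non-overlapping peaks tiled by ten 150-bp
  bins; 10% of peaks planted UP and 10% DOWN with bin fold changes
  `Normal(±1, 0.4)` and two-sided z-test p-values (known SD, so the null
  p-values are exactly uniform and FDR calibration is testable).
* **Cistromes** (`gen_cistromes`): 600 enhancers, 9 TFs, focal binding
  with probability 0.5, additional degree uniform on its range, and
  inactivation probability `plogis(-3 + 0.8 * n_bound)`. Because the
  logistic saturates at high degree, the bound and unbound top strata are
  near-ties; the bound/6–8 cell is the maximum in roughly 9 of 10 seeds.
* **Expression** (`gen_expression`): adult log2 baselines `Normal(8, 2)`;
  identity genes get a maturation loading uniform on 2–4 (others
  `Normal(0, 0.3)`), six reference stages interpolating newborn → adult
  with 3 replicates each and residual SD 0.3; a perturbation study with a
  per-gene `Normal(0, 1)` batch offset and identity genes repressed by the
  effect size; injury samples as convex newborn/adult mixes; and Poisson
  single-cell counts with lognormal size factors along a uniform
  maturation time.

What the generator does **not** emulate: read-level noise, peak-calling
artifacts, correlated bins, overdispersed counts, chromatin-state
confounders, or nonlinear developmental trajectories. Passing tests
demonstrate that the algorithms implement their contracts and recover
planted structure under these idealized conditions — not that any
particular biological dataset will behave as cleanly.

# Problem sizes and numerical choices

The test suite and the acceptance script sweep 20 seeds at the default
generator sizes above (2,000 genes × 10 tissues for identity; 10,000 bins
for the differential module; 600 enhancers × 9 TFs; 18 reference plus 15
injury samples for the projection), which keeps each sweep under a minute
while leaving planted-structure recovery far from its thresholds.
Tolerances: oracle-equivalence checks (interval merge, halfspace depth,
log-odds, tangent cutoff, Ward heights, PC1 variance fraction) are exact
to 1e-9; the tangent rule treats slopes within 1e-9 of 1 as reaching it;
the Haldane correction applies only when a zero cell exists; ties are
broken deterministically everywhere (leftmost peak, gene-id order,
depth-median distance then index).

# Known limitations

* Depth-based bagplot fences are hull-inflations, not the interpolated
  depth contours some implementations draw; bag membership (not the
  polygon) is the tested contract.
* The mean-only batch adjustment assumes the anchor condition really is
  equivalent to the reference's adult stage; violations bias all
  coordinates of that batch by a constant.
* The per-bin normal z-test used by the synthetic pipeline is a stand-in
  for a real count model and is only appropriate for the generator's
  known-SD Gaussian bins.
* GSEA FDR here is the single-set permutation estimate; multi-set
  integration is out of scope.
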