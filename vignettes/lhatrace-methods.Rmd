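---
title: "Quantifying projections to the lateral hypothalamus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying projections to the lateral hypothalamus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lhatrace)
```

## The problem

Retrograde viral tracing labels the somata of every neuron projecting to an
injected target — here the lateral hypothalamic area (LHA), the hub that
integrates cortical and limbic inputs into feeding and energy-expenditure
programs. Quantifying such an experiment brain-wide means turning a stack of
serial coronal fluorescence sections into a table of *neurons per anatomical
region per hemisphere*, robust enough to compare genotypes (e.g. an ALS
model against wild-type littermates). That requires a chain of steps, each
of which this package implements as a separately testable stage:

1. **Registration** of each 70-micron section to a coronal atlas plate via
   named anatomical landmarks.
2. **Parcellation** of the section into per-region crops.
3. **Pixel classification** to strip autofluorescent tissue architecture
   and dendritic debris from the labelled somata.
4. **Density counting**: a regression forest that integrates a learned
   per-pixel soma density rather than detecting individual cells.
5. **Volumetry and quality control** of the injection site.
6. **Normalisation and statistics** across the cohort.
7. Optionally, **misfolded-protein burden** scoring of cortical areas.

Because no raw dataset of this kind is publicly deposited, the package
pairs every stage with a synthetic-cohort generator that produces sections
with exact ground truth, so the whole chain can be validated quantitatively
offline.

## The atlas

`load_atlas()` reads a versioned JSON schema: a region ontology (unique
ids, acyclic parent links, a many-to-one pooling map) and a list of plates
ordered by decreasing anterior-posterior (AP) coordinate, each with named
landmarks and closed region polygons per hemisphere. The packaged atlas is
deliberately synthetic — half-ellipse brain outlines with rectangular
nuclei — but carries the real topology the analysis needs: 25 named regions
(prefrontal/orbital/insular areas anteriorly; motor and somatosensory
cortex; piriform cortex and taenia tecta; striatum; hypothalamic nuclei
including the LHA; amygdalar nuclei posteriorly) on 13 plates from
AP +2.6 mm to −3.0 mm. Two layout decisions matter downstream:

* The LHA outlines are sized so a serial 70-μm reconstruction of the intact
  LHA integrates to ≈2.75 mm³ bilaterally, the wild-type reference used by
  the atrophy compensation.
* The seven landmark names repeat on every plate, but their geometric
  configuration varies *non-affinely* along AP. This is essential: plate
  assignment minimises an affine fit residual, and affinely equivalent
  landmark sets would make every plate fit every section exactly.

Conventions: atlas coordinates in mm, `x` increasing rightward, `y`
dorsally; pixel space row-major with row 1 at the dorsal edge. A point on
the midline is assigned *ipsilateral* (deterministic tie-break). A pixel
belongs to a region iff its centre is inside the polygon under the even-odd
rule; a soma belongs to the region containing its centroid.

## Registration and parcellation

`fit_warp()` fits similarity, affine (default) or thin-plate-spline
transforms by least squares; the backward (atlas→section) direction is
fitted from the reversed correspondence rather than by numeric inversion,
so both directions are optimal in their own frame and the round-trip error
on noiseless landmarks stays below half a pixel. The affine default
reflects what landmark clicking can actually constrain on real sections;
TPS is available for deliberately distorted synthetic material but needs at
least four well-spread pairs and interpolates exactly (no smoothing), so
noisy landmarks should stay with the affine model.

`assign_plate()` selects the plate minimising the RMS landmark residual,
with exact ties resolved to the more anterior plate. `parcellate()` then
rasterises every leaf-region outline through the backward warp and cuts a
bounding-box crop per (region, hemisphere), padded by 8 px of context but
masked to the region, so later counting cannot leak across boundaries;
same-hemisphere leaf masks are disjoint by construction.

## Pixel classification and density counting

Both learned stages share a Gaussian-derivative feature bank at scales
σ = 1.0, 1.6, 3.5, 5.0 px: Gaussian smoothing, Laplacian of Gaussian,
gradient magnitude, difference of Gaussians (pair σ, 1.6σ), structure-tensor
eigenvalues (inner scale σ/2, outer σ) and Hessian eigenvalues — 32
channels in the default configuration. Filters are separable and applied
exactly through small banded convolution matrices with mirror borders, so
features are translation-equivariant away from the boundary.

The pixel classifier is a 100-tree (50 in the desk-scale demo
configuration) probability forest trained on sparse foreground/background
strokes; `segment()` thresholds the probability map at 0.5 by default and
flags empty masks so soma-free crops can be excluded downstream. The
forest size and threshold are package decisions — only the counting-stage
forest has published hyperparameters.

The counter follows the learning-to-count construction: each annotated
soma contributes a unit-mass Gaussian (σ_dot = 2 px ≈ one soma radius) to a
density target; a regression forest with **20 trees of maximum depth 80**
maps features to density; a crop's count is the integral of the predicted
density over its mask. Counts are therefore additive over disjoint masks by
construction, and predictions are clipped at zero (the clipped mass is
logged and stays below 2% on the synthetic benchmarks). Training subsamples
at most 1,200 px per image, stratified so that up to 60% carry positive
target mass; prediction runs at full resolution. **Accuracy** is defined
here — the original description never pins a formula — as the complement of
the mean relative count error over evaluation images,
`100 × (1 − mean |ĉ−c| / max(c, 1))`, with the `max(c, 1)` guard making
neuron-free tiles well defined. On the default synthetic tiles the 3-seed
median reaches ≥86% with 100 training images and ≥94% with 250, the
saturating learning curve the counting stage is known for.

## The synthetic cohort

`cohort_design()` fixes the generative conditions; its defaults are the
study conditions the analysis assumes:

* sections every 70 μm from AP +2.6 to −3.0 mm; 15 μm/px rendering;
* soma densities follow a fixed relative profile (limbic and orbital areas
  densest) scaled so a reference brain expects **50,000** labelled somata,
  80% of them ipsilateral (≈40,000 vs 10,000);
* per-region counts are Poisson (an optional negative-binomial size adds
  brain-level dispersion for power studies);
* genotype effects are multiplicative count factors per region; LHA atrophy
  scales the outline about its centroid so that *volume* scales by the
  stated factor (0.75 for the atrophic genotype by default — no magnitude
  is published, so this is a package choice);
* images are a smooth autofluorescence field plus Gaussian noise, somata as
  isotropic Gaussian blobs of radius 2–4 px, thin bright curvilinear
  dendritic fragments, and a bright spherical injection blob (0.5 mm³)
  centred in the LHA, with an optional dorsal backflow column along the
  capillary track;
* training tiles are 96×96 px with dot annotations spanning low to high
  density and ~10% neuron-free background tiles (mean 18 somata on
  non-empty tiles).

Seeds follow a cohort → brain → section hierarchy (a Lehmer step keeps all
derived seeds below 2³¹), so any brain regenerates bit-identically on its
own. What the generator does **not** emulate: optical blur anisotropy,
vascular autofluorescence, section tears and folds, capillary-track
infection, or touching somata that require instance separation. Passing
the synthetic benchmarks therefore demonstrates the pipeline's internal
consistency and statistical calibration, not parity with histological
ground truth.

## Volumetry, QC and region selection

Region volume is the summed cropped area times 70 μm. The injection site
is segmented by an absolute intensity threshold (half the rendered
injection intensity by default — the manual "set image contrast" of the
original protocol is not reproducible), keeping the connected component
containing the nominal centre plus dorsal components along the track.
A brain is excluded when the injection volume exceeds 1 mm³, the centroid
falls outside the LHA (the package's operationalisation of "mislocalised"),
the dorsal backflow exceeds 10% of the injection volume, or fewer than
25,000 labelled neurons are counted overall; all thresholds are strict
inequalities, exactly as printed, so boundary values pass.

Analysis regions are pooled (ORBl/ORBvl/AI as one orbital-insular whole,
PL/ORBm as another), filtered at a minimum reference-cohort mean of 100
counts, and ranked by that mean with ties broken by region id; the top 28
survive by default. The published 28-area list was fixed from the original
data, so deriving it from the cohort requires an explicit rule — rank by
reference-genotype mean is the one implemented.

## Normalisation and statistics

* **50k normalisation** divides each region count by the brain total and
  multiplies by 50,000; the normalised brain always sums to exactly 50,000.
* **Atrophy compensation** multiplies counts by (LHA volume)/2.75 mm³,
  implemented literally as the protocol sentence reads. That wording is in
  tension with a per-mm³ *density* reading (which would divide); the
  package exposes `mode = "density"` for comparison without endorsing it,
  and notes that the compensation ratio cancels under a subsequent 50k
  normalisation.
* **Two-way ANOVA** (genotype × structure, with interaction) with
  per-structure genotype contrasts
  `t = Δmean / sqrt(MS_res (1/n₁ + 1/n₂))` on the residual df and Sidak
  correction `p' = 1 − (1 − p)^m` over the structure family — the
  construction common graphing-statistics suites use. A balanced
  2 × 28 × 3 layout yields the familiar F(1, 112). Unbalanced layouts use
  Type-II sums of squares with the fitted layout's residual df.
* **Pooled-variance t-tests** from raw values or from printed summary
  statistics (the human volumetry comparison 750.8 ± 74.3 (n = 72) vs
  886.9 ± 86.5 (n = 43) reproduces |t| = 8.9 on 113 df from summary
  statistics alone).
* **One-way ANOVA + Tukey HSD** for the burden comparison.

A calibration caveat, decided a priori and enforced by the benchmarks: the
pooled-MS post-hoc assumes homoscedastic structures. Count data spanning
orders of magnitude violate that (Poisson variance tracks the mean), making
the largest structures anticonservative. The operating-characteristic
simulations therefore use exchangeable structure baselines (equal means,
700 counts), which isolates the genotype contrast the test is meant for:
under the null the family-wise false-positive rate stays ≤7% over 500
simulated cohorts, and a 1.8× expansion of the orbital-insular pool at
n = 6 per genotype is detected (Sidak p < 0.05) in ≥80% of cohorts. With
strongly heterogeneous baselines the same battery would inflate the
family-wise rate; that is a property of the published construction, not of
this implementation, and log- or root-transforms would be the standard
remedy if calibration on raw heterogeneous counts were required.

## Burden scoring

`burden_fraction()` runs rolling-ball background subtraction — grayscale
opening with a true non-flat ball of radius 20 px, not a legacy
shrink/enlarge approximation — then a Renyi-entropy threshold on the
256-bin histogram of the corrected image, and reports the suprathreshold
area fraction. The threshold combines the entropy-maximising splits at
orders α→1 (the Shannon/Kapur limit), ½ and 2 with the published
order-dependent weighting of the sorted candidates. The protocol sentence
reads "thresholding … and subsequent background subtraction", which is
backwards relative to standard practice; the package subtracts first by
default and offers `literal_order = TRUE` to reproduce the literal reading.
Constants of the combination rule vary slightly across published
descriptions; the implementation pins the classical one and claims
equivalence with no specific legacy plugin.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains all stages from a single configuration and seed,
checkpoints per-brain tables as CSV/JSON under the output directory
(reruns with an identical configuration hash reuse them), and writes a
manifest with output checksums; `make_report()` collates the run into the
panels a cohort study reports. Every stochastic stage draws its seed from
the global one, so a rerun reproduces identical tables.

Problem sizes in the shipped tests and benchmarks are chosen at desk
scale as the package's own validation conditions: the counter benchmark
trains on 250 and evaluates on 100 tiles of 96×96 px across 3 seeds;
image-level round-trip tests use a hypothalamic AP window (−0.6 to −1.8 mm)
at 20 μm/px; the end-to-end demo cohort runs 2 brains per genotype on six
sections each at 30 μm/px with proportionally reduced totals and QC
thresholds. Full-scale cohorts (81 sections per brain, 50,000 somata) are
supported by the same code paths and are exercised truth-only where images
are not required.

## Known limitations

* The toy atlas has ~20 leaf regions, not the 84 cerebral areas a full
  reference ontology yields; the 28-area selection rule is therefore
  exercised at reduced k in the demo configuration.
* No brainstem: the original analysis excluded it as unreliable, and the
  atlas simply does not model it.
* Somata spanning adjacent 70-μm sections may be counted twice; the method
  counts per section and no correction is attempted (none is published).
* The density counter is validated on rendered Gaussian somata; real
  soma morphology, occlusion and staining variability will lower accuracy
  in ways the synthetic benchmark cannot measure.
* Registration assumes landmark correspondences; intensity-based
  registration and 3-D tilt correction are out of scope.
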