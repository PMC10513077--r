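---
title: "Quantitative podocyte phenotyping: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative podocyte phenotyping: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`podometrics` packages the quantitative machinery of a deep-learning-assisted
podocyte phenotyping workflow: segmentation of glomerular tufts and podocyte
nuclei in WT-1/nephrin-stained micrographs, per-glomerulus 2D morphometry,
model-based stereological extrapolation to 3D, filtration-slit density from
STED-like z-stacks, plate-reader urine-chemistry calculations, a single-cell
QC filter, and a pre-test screening decision tree for multi-group statistics.
Every stage can be exercised on seeded synthetic data with exact ground
truth, which is how the test suite and the acceptance script validate the
pipeline.

# The synthetic scenes

Real inputs are fluorescence micrographs saved as 2048 x 2048 frames at
8.8 px/um, with WT-1 marking podocyte nuclei and nephrin the podocyte
cytoplasm. The generator emulates these as smoothed indicator functions plus
additive Gaussian noise: elliptical tufts with a dim cytoplasmic plateau,
bright nuclear blobs inside them (WT-1 channel), and a textured bright
cytoplasm with dimmer nuclei (nephrin channel).

The test-scale defaults were chosen once and kept: 512 x 512 frames at the
real 8.8 px/um (so all area/length conversions are exercised at the true
resolution), tuft semi-axes 7-10 um, 4-8 nuclei of semi-axis 1.0-1.5 um per
tuft, noise SD 0.05 on a 0-1 intensity scale. The geometry is a scaled-down
glomerulus: real mouse glomerular profiles (radius ~40 um) would not fit
several to a 512-px test frame, so tufts are smaller while the
nucleus-to-tuft radius ratio (~0.13) and the signal-to-noise ratio (object
amplitudes 0.5-0.7 over background ~0.08, noise 0.05 — a clean
immunofluorescence stain) stay realistic. Nuclei are placed with a minimum
centre separation so blobs stay resolvable; `edge_touch_fraction` and
`merged_pair_fraction` deliberately inject the two failure modes the
post-processing must exclude. A merged pair is drawn as two overlapping
ellipses sharing one label, with centre distance 0.9 x the sum of the
smaller semi-axes so the union is always one dumbbell-shaped component.

What the generator does *not* emulate: optics point-spread functions,
staining chemistry, intensity gradients across tissue, out-of-focus light,
or touching nuclei in dense clusters. Passing tests therefore demonstrate
that the estimators are correct on data satisfying their geometric
assumptions, not that the trained network transfers to real histology.

# Segmentation network and weight maps

The segmenter is a three-level fully convolutional encoder-decoder with skip
connections (two 3x3 conv + ReLU blocks per level, 2x2 max-pooling,
nearest-neighbour upsampling, channel widths 8/16/32 by default), trained
with per-pixel weighted cross-entropy and Adam on randomly augmented 96-px
patches. The loss weight map is

w(x) = w_c(x) + w0 * exp( -(d1(x) + d2(x))^2 / (2 sigma^2) ),

where `w_c` balances class frequencies (inverse-frequency weights, capped at
20 so sparse nuclei do not dominate) and `d1`, `d2` are Euclidean distances
to the nearest and second-nearest labeled object; with fewer than two
objects the border term is zero. The constants w0 = 10 and sigma = 5 px are
the standard choice for this weight-map scheme. Augmentations default to
flips and 90-degree rotations; the elastic deformation is implemented
(coarse Gaussian displacement fields, bilinear/nearest interpolation) but
disabled by default because the synthetic objects are already pose-randomised.

Training splits scenes 80/20 by scene, seeded; validation scenes contribute
no patches. The acceptance settings — 20 scenes, 2 epochs x 25 steps x 4
patches for tufts and 4 epochs for nuclei — are the sizes at which the
synthetic benchmark reaches tuft Dice >= 0.85 and <= 10% held-out nucleus
count error on one CPU; they are desk-scale choices, not claims about
training real networks.

# Morphometry and exclusions

Connected components of the binary tuft prediction are labeled and filtered:
components touching the frame within `edge_margin_px` (default: any direct
touch) are excluded as edge-cut; components with area above `max_area_um2`
or solidity (pixel area / convex-hull area) below `min_solidity` are
excluded as merged. The defaults — 320 um^2, roughly the 99th percentile of
synthetic singleton areas (pi * 10^2), and solidity 0.95 — cleanly separate
the two populations in the generator (singletons >= 0.987, merged pairs
<= 0.94). Whether the original workflow used area, solidity or manual review
for merged structures is not stated anywhere; this criterion is this
package's own, and both knobs are exposed.

Per retained glomerulus the records are: tuft area (pixel count / ppm^2),
podocyte count (nucleus components whose centroid falls inside the tuft —
centroid membership is unambiguous when nuclei straddle the tuft border),
mean nuclear profile area, areal density (reported per 10^4 um^2, a unit
choice made here), nuclear/tuft area ratio, and the nephrin-positive
cytoplasm area within the tuft from an Otsu threshold computed on the
intensity histogram restricted to that tuft. Cytoplasm area includes nuclear
pixels (no subtraction). A constant intensity inside a tuft makes Otsu
degenerate; the record is flagged and the area set to zero. The Otsu
implementation maximises between-class variance over midpoints between
occupied intensity levels (binning to 256 levels for continuous data), with
ties broken toward the lowest cut; it is tested against an independent
exhaustive within-class-variance minimiser.

# Stereology

The 3D extrapolation is deliberately classical model-based stereology:

* tuft volume V = (beta / k) * A^(3/2) with the sphere shape coefficient
  beta = 1.38 and size-distribution coefficient k = 1 (Weibel-Gomez);
* podocyte nuclei modeled as spheres, so the mean random-section area
  (2/3) pi R^2 inverts to the mean caliper diameter D = 2 sqrt(3 a / (2 pi));
* numerical density N_V = N_A / D, volume density V_V = A_A (Delesse), and
  total count N = N_V * V.

The source workflow cites but does not print its stereology formulas, so
agreement with its published figures is not claimable; this estimator family
was chosen because it is standard and admits an exact simulation oracle
(`simulate_sphere_sections` cuts a known sphere population with random
planes and the module recovers the true count within 10% at >= 100
sections). Ellipsoid shape corrections and disector methods are out of scope.

# Slit density

STED-like z-stacks are merged by maximum-intensity projection (the
projection operator is a design choice; the source states only that slices
were "merged"), binarised with the same Otsu operation, thinned to a 1-px
skeleton (Zhang-Suen plus a staircase-pruning pass that removes redundant
corner pixels while preserving 8-connectivity), and measured as length per
field area. Length sums adjacent skeleton pairs — 1 px for 4-neighbours,
sqrt(2) for diagonals — skipping diagonal pairs already connected through a
shared 4-neighbour, which would double-count corners. Axis-aligned and
diagonal runs are exact by construction; digitised circles measure within
~5% for stroke widths of 4-7 px and within 10% at 3 px. Aggregation follows
the sampling plan of five fields per glomerulus and at least five glomeruli
per mouse, with hierarchical field -> glomerulus -> mouse means and warnings
when the plan minima are not met.

# Assay calculations and the QC filter

Kinetic colorimetry: BUN signal = ((A60 - A120) - blank) * 0.467 and
creatinine signal = (A120 - A60) - blank, each mapped to mg/dL by linear
least squares through the standards (the 0.467 factor is applied before the
regression; the source prints both steps without ordering them). The
albumin ELISA dilution rule is piecewise in blood glucose — <200 mg/dL
1:150, 200-350 1:250, >350 1:500 — with the 200-350 interval read as
closed, so exactly 200 and exactly 350 both map to 1:250 (the printed
notation is ambiguous at 200). Linear rather than four-parameter-logistic
standards are used for albumin too, matching the wording for the other two
assays. The ACR divides albumin (ug/dL) by creatinine (mg/dL) and is
reported as ug/mg. The single-cell QC filter keeps cells with a
mitochondrial read fraction strictly below 0.40 and strictly more than 200
expressed genes, identifying mitochondrial genes by a case-insensitive
`mt-` prefix (mouse convention).

# The statistics decision tree

Before any comparison, every group is screened: Grubbs' two-sided outlier
test (at most one flag per group; the flagged value is removed once by
default, since the source does not state its handling, and removal can be
switched off), Anderson-Darling plus Shapiro-Wilk normality in every group,
all at the screening level described below,
and the Brown-Forsythe variance test. Normality requires BOTH tests to pass
in EVERY group. Branches: normal + homoscedastic -> one-way ANOVA with
pooled-variance pairwise t tests, Bonferroni-adjusted; normal +
heteroscedastic -> Welch ANOVA with Games-Howell pairwise comparisons
(Welch-Satterthwaite df, studentized-range p-values); otherwise ->
Kruskal-Wallis with Bonferroni-adjusted Mann-Whitney-U pairs (the
nonparametric adjustment is a choice made here). Significance codes use the
strict thresholds ns / * / ** / *** / **** at 0.05 / 0.01 / 0.001 / 0.0001.

The tests run at alpha = 0.05, but the screens (normality, variance, and
the tree's Grubbs pass) use their own `screen_alpha = 0.01`: six
distributional screens applied in conjunction at 0.05 would pass jointly on
only ~74% of perfectly normal three-group datasets (0.95^6), misrouting a
fifth of them to less powerful branches, and removing a "flagged" extreme
value from 5% of perfectly normal groups measurably inflates the
downstream F test (null rejection ~6.1% instead of ~5.1%), so the screens
are set to catch gross violations only. With that separation the
tree routes three Normal(0,1) groups (n = 50) to the parametric branch in
~95% of replicates, an exponential group to Kruskal-Wallis in ~97%, and a
25-fold variance ratio to Games-Howell in ~96%, with an omnibus type-I
error of ~5% over 1000 null replicates. Anderson-Darling is undefined below
n = 8; for such groups Shapiro-Wilk alone decides. Two-group inputs are
allowed (the omnibus reduces to the two-sample case).

# Pipeline and reproducibility

`run_pipeline()` chains generate -> train -> segment -> morpho -> stereo ->
slit -> assay -> stats with per-stage toggles, writes one CSV/JSON per
stage plus a manifest (config hash, seed, row counts), marks failures with
a `FAILED` file naming the stage, and — because every stochastic call
funnels through a single seeded generator with save/restore semantics —
reproduces all non-training CSVs bit-identically for a fixed config and
seed. When the segmentation stages are disabled the morphometry stage runs
on the ground-truth masks, which keeps the bundled demo configuration
(`inst/extdata/demo_config.yaml`) under a few seconds. A thin command-line
wrapper lives at `inst/scripts/podometrics.R`.

# Numerical notes and limitations

* Coordinates are pixel-centre, 0-based conceptually, row-major in R;
  areas are pixel counts, so all area recoveries carry pixelation error
  (the 10-um disk test tolerates 1%).
* `with_rng()` restores the caller's RNG state, so library calls never
  perturb user randomness.
* Degenerate inputs are explicit: constant intensities flag Otsu, constant
  samples warn in Grubbs, empty masks give zero length, infeasible packing
  and non-finite training losses abort with diagnostics.
* The skeleton length estimator is biased upward by a few percent on
  strongly curved thin ridges; widths of 4-7 px are its comfort zone.
* The conv-net is CPU-sized (about 60k parameters); it is meant to validate
  the training/inference machinery on synthetic scenes, not to reach
  state-of-the-art histology segmentation.
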