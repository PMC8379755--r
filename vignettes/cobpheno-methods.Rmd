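---
title: "Methods: post-segmentation phenotyping of maize cob images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-segmentation phenotyping of maize cob images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genebank collections of maize landraces are documented by photographs: each
accession is laid out as 1–12 cobs side by side with a ruler, under highly
variable backgrounds, resolutions and lighting. Turning such images into
quantitative phenotypes requires (i) an instance mask per cob and per ruler
part, (ii) a pixel-to-centimeter calibration from the ruler, (iii) a small
set of reproducible shape and color descriptors per cob, and (iv) a way to
flag accessions whose cobs are phenotypically heterogeneous — a signature of
admixed seed lots or within-accession genetic diversity.

`cobpheno` implements everything downstream of segmentation, a classical
graph-based segmenter as a built-in baseline, mask-level evaluation metrics,
and a synthetic scene generator with analytic ground truth so that the whole
chain can be validated without any proprietary image collection.

## Synthetic scenes and what they emulate

Real cob silhouettes are commonly described by parametric profile equations
(as in avian egg morphometrics). We use a two-parameter family: the
half-width at normalized position $t \in [0,1]$ from the apical tip is

$$h(t) = \frac{D}{2}\,\bigl(4u(1-u)\bigr)^{1/p}, \qquad u = t^{\gamma},$$

where $D$ is the maximum diameter, $p$ controls fullness ($p = 2$ is an
exact ellipse; larger $p$ approaches a barrel) and $\gamma \ge 1$ warps mass
toward the base, creating asymmetry ($\gamma = 1$ is mirror-symmetric).
Because $u$ sweeps all of $[0,1]$, the maximum half-width is exactly $D/2$
for every $(p, \gamma)$.

A scene renders its cobs vertically, apical ends aligned on a baseline, next
to a two-part ruler (one horizontal, one vertical strip of alternating black
and white square elements of 1 cm by default — the element size is
configurable because real chart rulers vary). Backgrounds are uniform
mid-tone colors with Gaussian noise, cob colors come from a natural palette
(white through yellow, orange, red, brown, purple) with per-pixel speckle
emulating kernel texture. The default sampling ranges are the study
conditions used throughout the tests: 1–12 cobs per image, lengths 8–30 cm,
diameters 3–8 cm, $p \in [1.5, 4]$, $\gamma \in [1, 2]$, scale 8–15 px/cm,
background noise sd 5.

Ground truth is analytic: a pixel belongs to a cob mask iff its center lies
inside the continuous silhouette, and the true traits are computed from the
continuous profile by numeric integration (2000-point midpoint rule), so
they are independent of the rendering resolution. Deliberately **not**
emulated: perspective, rotation, shadows, kernel-level texture structure,
touching cobs, damaged rulers. Passing the round-trip tests therefore shows
the measurement chain is unbiased on clean geometry; it does not certify
performance on degraded archive scans, which is exactly the regime where
classical segmentation is known to need per-dataset tuning.

## Built-in segmentation

The baseline segmenter is the Felzenszwalb–Huttenlocher graph algorithm:
8-connected grid graph over Gaussian-smoothed channels (separable kernel,
radius $\lceil 3\sigma \rceil$, reflected boundaries), edge weight =
Euclidean RGB distance, edges processed in nondecreasing weight order,
merging components when
$w \le \min\!\bigl(\mathrm{Int}(C_1) + k/|C_1|,\ \mathrm{Int}(C_2) + k/|C_2|\bigr)$,
followed by a pass absorbing components below `min_size` into their most
similar neighbor. Ties in edge weight are broken by construction order via a
stable sort, so segmentation is fully deterministic; a brute-force replay of
the merge rule on 3×3 images is part of the test suite.

Defaults ($k = 300$, $\sigma = 0.6$, `min_size` 30) were chosen on synthetic
scenes only: $\sigma$ small enough that 8 px ruler elements survive
smoothing, `min_size` below the smallest element area at 8 px/cm, $k$ large
enough to absorb speckle within a cob yet far below the color contrast
between cobs, background and ruler elements.

Instance assembly is rule-based and deliberately transparent:

* **background** — segments covering > 5 % of the image border, plus
  segments within RGB distance 25 of the dominant border color. The
  tolerance is intentionally tight: dark purple cobs on dark backgrounds sit
  only ~40 RGB units away.
* **ruler** — groups of ≥ 3 adjacent achromatic segments containing both
  dark and light members (the alternating-element test); each group becomes
  one instance. The instance mask is the group's **filled bounding box**: a
  ruler part is a rectangular strip, and the mid-gray transition segments
  between elements (which are neither dark nor light) would otherwise punch
  holes into the mask and bias calibration.
* **cobs** — remaining segments grouped by adjacency (3 px), keeping groups
  above 0.05 % of the image area; segments overlapping a detected ruler's
  box are treated as element debris, not cobs.

## Calibration and the eight traits

Calibration binarizes the grayscale within each ruler mask (Otsu threshold
restricted to mask pixels), labels connected components of both polarities,
and averages their extents along the strip axis: `px_per_cm` = mean extent /
element size. Two numerical safeguards matter in practice: the mask is
eroded by 2 px first (stray border pixels otherwise bridge same-polarity
elements along the strip edge — we observed up to +90 % scale error without
this), and the two end components of each strip are discarded because only
interior elements are delimited by exact element-to-element boundaries on
both sides. Fewer than 3 valid elements yields an *uncalibrated* scale;
traits are then reported in pixels and flagged, never silently dropped.

Per cob mask the extractor computes, from the principal-axis width profile:

| trait | definition | units |
|---|---|---|
| length | extent of pixel centers along the principal axis + 1 px pitch | cm (px if uncalibrated) |
| diameter | maximum cross-sectional width | cm |
| aspect ratio | length / diameter | — |
| asymmetry | $\sum_b \lvert w(t_b) - w(1-t_b)\rvert \,/\, 2\sum_b w(t_b)$ | —, 0 = symmetric, ≤ 1 |
| ellipticity | mask area / $(\pi LD/4)$ | —, 1 = ellipse, > 1 fuller |
| mean R, G, B | channel means over the complete mask | 0–255 |

The asymmetry and ellipticity statistics are this package's
operationalization of the egg-morphometrics idea: both are anchored (0 and 1
for a symmetric ellipse), scale-free, and recoverable from the generator's
continuous profiles, which makes round-trip testing well-posed. The complete
mask is used for color because kernel color varies along diverse cobs.
Diameter is the *maximum* width rather than the mean — the two are nearly
collinear on cob shapes, and the maximum matches how calipers are used;
`width_profile()` exposes the full profile if a different summary is wanted.

One numerical detail: widths are first accumulated in bins of almost exactly
one pixel pitch and only then aggregated to the requested $B = 100$ bins.
Bins slightly wider than one pitch alias against the pixel grid (two pixel
rows occasionally fall into one bin), which inflated the diameter by tens of
percent before this was fixed. The profile is oriented with $t = 0$ at the
narrower (apical) end; orientation affects no trait magnitude since the
asymmetry statistic is mirror-invariant.

Per-image summaries average over **all** detected cobs, false positives
included; when the input masks come from a segmenter under evaluation this
deliberately penalizes spurious detections. Sample standard deviations use
$n - 1$ and are flagged `NA` for single-cob images.

## Evaluation metrics

Mask IoU is plain pixel counting. Matching is greedy per class by descending
confidence, each prediction taking the unmatched ground truth with maximal
IoU provided IoU ≥ threshold; we use the inclusive rule because it is the
common convention and consistent with the worked single-pair example
(IoU = 0.60 → true positive at thresholds 0.50–0.60, giving AP 30.0).
`AP@[.5:.95]` averages precision over the ten thresholds 0.50–0.95 and over
ground-truth classes (macro). This is the plain mean-precision reading;
COCO-style PR-curve integration and micro-averaging are available behind
flags for comparability with detection benchmarks.

## Heterogeneity clustering

Two independent routes, intentionally different in what they cluster:

1. **Z-score route** — each cob's traits are standardized within its image,
   $Z_{ij} = (x_{ij} - \bar X_j)/S_j$ (sample SD). Cob-level Z-scores are
   clustered with CLARA (PAM on subsamples, Euclidean, best sample by total
   dissimilarity), with $k$ chosen by the average silhouette over 2–8.
   Images with fewer than two cobs or a zero SD in any trait carry no
   within-image signal and are excluded with a logged count.
2. **SD route** — the per-image SD of each trait, centered and scaled
   column-wise, clustered with k-means (10 restarts), $k$ chosen by the gap
   statistic with 50 uniform reference draws in the PCA-aligned bounding box
   and the one-standard-error rule.

Clustering runs in full trait space; PCA (`pca_view()`) is used for
visualization only. Projecting onto leading components first would add an
arbitrary cutoff without changing the Euclidean geometry the methods use.

The planted-data generator used to validate the routes models heterogeneous
accessions as **two-morph admixtures** — the biologically stated cause of
within-accession diversity — rather than as a single wide Gaussian: each
heterogeneous image draws cobs from two morphs whose separation and
within-morph spread combine to the target SD. Morphometric SDs are inflated
3-fold and color SDs 6-fold relative to homogeneous images (mean inflation
≈ 4×, color strongest, matching the observation that cob color is the most
variable trait within accessions). Under this design both routes select
$k = 2$ and the SD route recovers the planted regimes with ARI > 0.97
across seeds.

## Problem sizes and reproducibility

The validation workloads are sized for a desk machine: the end-to-end
recovery benchmark uses 100 scenes (≈ 1 minute on one CPU), the clustering
benchmark 450 images / ≈ 3300 cobs (≈ 15 s), and all property tests run on
fixtures of a few hundred pixels. Every random step — scene sampling,
rendering noise, CLARA subsampling, k-means restarts, gap references — takes
an explicit integer seed, and identical seeds reproduce images, truth tables
and cluster outcomes byte for byte.

## Known limitations

* The segmenter's assembly rules assume cobs do not touch each other or the
  image border, and that the ruler is a two-part strip of alternating
  achromatic elements; heavily degraded scans will need parameter tuning
  (`fh_params()`), which is inherent to classical segmentation.
* Calibration assumes square ruler elements of known physical size; scales
  from fewer than 3 clean interior elements are refused rather than guessed.
* Trait accuracy degrades below ~8 px/cm as cob tips thinner than one pixel
  are unrenderable and unmeasurable.
* The gap statistic is by far the most expensive selection step
  ($B$ reference k-means runs per candidate $k$); reduce `B` for quick
  exploration at some loss of selection stability.
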