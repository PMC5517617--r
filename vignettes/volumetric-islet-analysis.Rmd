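---
title: "Volumetric islet morphometry and innervation analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric islet morphometry and innervation analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tissue clearing makes whole organs optically transparent, so a confocal
stack of a cleared pancreas contains every islet of Langerhans in the
sample rather than the handful that land on a thin histological section.
Exploiting that requires automation: thousands of islets per organ must be
segmented, measured, and scored for surrounding neural (neural-crest
derived) signal without manual intervention. `voxislet` implements such a
pipeline, together with the two simulation studies that quantify what
volumetric measurement buys over section-based histology, and the
first-order kinetics fit used to compare clearing protocols.

Because no public imaging dataset accompanies this problem, the package is
organized around a synthetic-volume generator with exact ground truth.
Every stage of the pipeline is validated against that ground truth or
against an independent oracle (brute-force voxel counting, closed-form
geometry, analytic power calculations).

## The detection pipeline

1. **Load and normalize.** Channels arrive as multi-page TIFF stacks with a
   stated voxel size (the package convention is 5 µm isotropic: the
   in-plane scale at which 20 px = 100 µm, and the usual confocal z-step).
   Each volume is rescaled so its upper reference quantile maps to 1.0.
   The default quantile is 0.999 rather than the maximum: the normalization
   compensates staining and expression variability between samples, and a
   quantile is robust to isolated hot pixels. The transform is monotone, so
   thresholds see the same ordering.
2. **Optional in-plane downsampling** (bilinear), for organ-scale volumes
   too large to process at native resolution. Scaling applies to x,y only
   by default — the z axis is already coarse — with the voxel size rescaled
   so physical extents are preserved; a flag enables 3D downsampling.
3. **MIP sectioning.** The volume is partitioned into consecutive z-slabs
   of 150 µm (three standard deviations beyond the mean islet size, so a
   section almost always contains a whole islet's equatorial profile) and
   each slab is maximum-intensity projected. The final, possibly shorter
   slab is kept: discarding tissue would bias organ-level counts.
4. **Section segmentation.** Global Otsu threshold on a 256-bin histogram,
   one erosion-then-dilation pass with a 3×3 square element, 8-connected
   component labeling, and a 5-pixel minimum region size. (At 5 µm/px,
   5 px = 125 µm², roughly one endocrine cell.) Constant sections — the
   degenerate Otsu case — yield no candidates.
5. **Per-islet refinement.** Each candidate's bounding box, padded by 20 px
   (100 µm) per side and clipped to the image, is re-projected over the
   candidate's section z-range and re-thresholded by Otsu *on the padded
   crop* (the local threshold adapts to local background). A
   dilation-then-erosion pass removes noise, and the connected component
   overlapping the original candidate is kept — never the union with a
   neighbor. The two stages deliberately use opposite morphology orders;
   both are configurable.
6. **Morphometry.** The refined region's convex hull is computed and its
   *pixel* area (number of grid pixels whose centres fall inside the hull,
   the discrete convex area) defines the circle-equivalent radius
   `r = sqrt(hull_area / pi) * pixel_size`. A moments-based ellipse
   (semi-axes from the second central moments, so a disk of radius r has
   both semi-axes r) is also recorded.

Sections are analyzed independently, as the per-section design dictates, so
an islet spanning a slab boundary is recorded twice. `deduplicate_islets()`
offers the post-hoc correction (flag the smaller of two adjacent-section
records whose centroids fall within one mean radius), but it is off by
default: fidelity to the per-section method is preferred, with the
correction available and its effect reported by the analysis scripts.

## Innervation scoring

Each islet's *neighborhood* is its filled convex hull offset outward by
2 px (10 µm), implemented as an exact Euclidean-distance dilation, and
includes the islet interior: nerve signal both surrounding and within the
islet counts. Positive nerve pixels are found with a local-arithmetic-mean
adaptive threshold (51 px block, offset 0; all three parameters exposed).
A pixel is positive when *strictly* above its local mean plus the offset —
strictness matters, because a flat (e.g. empty) section must produce no
positives. The local mean uses replicate boundary padding, so scores are
exactly translation invariant away from image borders. Each positive
region is then eroded by 1 px (5 µm) to suppress speckle.

The interaction (innervation) score is the count of surviving positive
pixels inside the neighborhood divided by the islet's own pixel area. It
can exceed 1 — the neighborhood is larger than the islet — and is zero
exactly when the nerve channel is empty.

**Artifact exclusion.** Two per-record criteria are computed: the positive
pixel fraction of the neighborhood, and the Shannon entropy (256-bin
histogram, bits) of the nerve crop over the neighborhood. Records beyond
`mean + 3 sd` of a reference population on either criterion are flagged —
not deleted. The reference is a held-out dataset when supplied, else the
pooled current experiment; thresholds are computed once and reused across
samples. The standard deviation uses the population (denominator-n) form,
which makes thresholds invariant to duplicating the reference. With
Gaussian scores the rule flags about `2 * pnorm(-3)` ≈ 0.27 % of records,
which the tests verify by Monte Carlo. Whether the positive-fraction
criterion should be computed over the neighborhood or the whole crop is
underdetermined; the neighborhood is used, matching the quantity the score
itself is built on.

## The simulation studies

**Resampling power.** `sampling_experiment()` emulates a manual experiment
of size n: draw n islets with replacement from each of two populations,
compare means with a two-tailed unpaired t-test (classic equal-variance
form, as the phrase "Student's t-test" implies; Welch by flag), repeat 100
times, and report the fraction significant plus the min-max range of the
per-repetition means. Min-max is used for the "range of the mean";
reporting an interval statistic instead would be a one-line change, and
min-max is the stricter, more conservative reading. Against an analytic
power oracle (`power.t.test`) the simulated power agrees within
Monte-Carlo error.

**2D-vs-3D section bias.** `virtual_sections()` cuts MIP slabs of a given
thickness starting at z = 0 and samples them (every third by default,
giving the count scale factor: total slabs over sampled slabs).
`compare_2d_3d()` detects islets on each virtual section (r2D), then
re-analyzes each detection with the same x,y bounding box but a z-range
extended by the mean islet radius plus three standard deviations on each
side (r3D). The extension statistics come from a full-depth detection pass
on the same sample — self-contained, mirroring how the 150 µm convention
itself is derived. Pairs are classified with a 10 µm size threshold
(roughly one endocrine cell: anything smaller is a staining artifact, not
an islet) and a 10 % relative tolerance:

| condition | class |
|---|---|
| r2D < 10 and r3D < 10 | excluded_small |
| r2D < 10 ≤ r3D | false_negative |
| r3D < 10 ≤ r2D | false_positive |
| both ≥ 10, within 10 % | within_tolerance |
| both ≥ 10, r2D low | underestimate_gt_10pct |
| both ≥ 10, r2D high | overestimate_gt_10pct |

The six rules are mutually exclusive and exhaustive, which the tests check
on 10⁴ random pairs. Overestimates (possible when a MIP slab is wider than
an islet and captures a neighbor's flank, or from hull discretization) are
reported as their own class rather than folded into "within tolerance".
The per-islet underestimation factor is `(r3D − r2D) / r3D`.

`simulate_section_bias()` is the geometric counterpart: spheres cut by
uniformly positioned slabs, apparent radius `R·sqrt(1 − (d/R)²)` with d the
slab-to-centre distance. In the thin-slab limit the mean apparent/true
ratio is the chord average `E[sqrt(1 − u²)] = π/4 ≈ 0.785`, an exact
anchor the Monte Carlo must hit within 1 %; the mean underestimation is
non-increasing in thickness and vanishes as slabs approach the volume
depth. The image pipeline reproduces the same pattern qualitatively; its
per-thickness means are noisier because few synthetic islets stand in for
thousands of real ones.

**Top-k comparison.** `top_k_comparison()` asks whether measuring only the
largest structures escapes the bias: per section the largest
`min(k, available)` radii (ties broken by islet id for determinism) are
averaged and the pooled 2D top-k set is compared against the 3D top-k set
with a two-sided Mann-Whitney test.

## Clearing and staining assays

`fit_clearing_rate()` fits `y = y_max (1 − exp(−k t))` — clearing as a
single-reactant first-order transformation — by Levenberg-Marquardt with
multi-start initialization (`y_max₀ = max(y)`, `k₀ = 1/median(t)`, times
{0.25, 0.5, 1, 2, 4} perturbations on k), keeping the converged fit with
the lowest SSE; non-convergence from every start is an error listing the
starts. An all-zero series returns a fit flagged degenerate rather than an
error, since an assay that simply failed to clear is a data point, not a
bug. Absorbance values are fitted raw (no transmittance transform).
`normalize_rate()` divides by a reference fit's k. Rescaling time units
rescales k exactly inversely, which the tests verify.

`staining_snr()` quantifies stained sections: Otsu threshold, 1 px
erosion, morphological closing, region properties, exclusion of
non-cellular features by size (default 20-2000 px) and roundness
`4π·area/perimeter²` ≥ 0.5. The perimeter is estimated as the count of
4-adjacent object/background pixel edges times π/4, an estimator unbiased
for digitized disks (the naive edge count would make squares look rounder
than circles). The ratio is mean intensity over retained regions divided
by mean intensity over everything else — the full exterior, not an
annulus, matching "extracellular background". With no surviving region the
ratio is flagged undefined, never silently 0.

## The synthetic generator

`generate_islet_volume()` draws islet radii from a truncated lognormal
(default median 40 µm, log-sd 0.35, truncated to 10-150 µm — the
tens-to-hundreds-of-µm range of developing islets), places spheres by
rejection sampling under a minimum surface-gap constraint (default 25 µm;
10,000 attempts per islet, then a hard error naming the constraint — a
deterministic failure beats a silent infinite loop), and rasterizes in
physical coordinates so spheres stay round under anisotropic voxels. Nerve
signal is a spherical-cap partial shell of configurable thickness (10 µm
default) covering each islet's drawn innervation fraction with an exact
voxel count, plus optional unassociated random-walk filaments. Background
noise is Gaussian, sd 2 % of the channel maximum, clipped to [0, 1] —
enough to be nonzero, small enough that Otsu stays stable. Placement can
optionally be constrained in the x,y projection (`xy_separation`), the
regime in which "well-separated" count-recovery guarantees are
well-defined, and spheres may be allowed to clip the axial faces
(`z_contain = FALSE`) as real islets at a block face do.

What the generator does **not** emulate: the optical physics (PSF,
depth-dependent attenuation, refractive artifacts), acinar/ductal
anatomy, non-spherical islets, and the true texture of nerve signal — no
quantitative description of that texture exists to copy, so the
shell-plus-filament model is a stand-in. Passing tests therefore show the
pipeline is correct on its stated geometric model, not that it would
segment any particular real dataset well; parameters are exposed
precisely so they can be retuned on real data.

## Numerical choices and conventions

- Coordinates: 1-based voxel indices in code; the physical centre of voxel
  i is `(i − 0.5) × spacing` µm. Grids are indexed `[x, y, z]`.
- Otsu on 256-bin histograms of the (rescaled) section; constant input
  returns an infinite threshold, i.e. an empty mask, with a logged message.
- Connectivity: 8-connected in-plane labeling (4-connected available).
- TIFF storage: 32-bit float pages on the normalized [0, 1] scale;
  round trips are exact to float precision.
- The 5-pixel minimum at 5 µm/px corresponds to 125 µm²; the pixel-count
  rule is the normative one.
- Sampling simulations use a single seeded generator per run with the seed
  recorded in the result object.

## Problem sizes

The test-suite and acceptance fixtures use desk-scale versions of the
study: 50 spheres in a 3 × 3 × 0.15 mm single-section volume for count and
radius recovery; a 1 × 1 × 0.6 mm volume with 12 islets for the
image-based thickness sweep; 10⁵ Monte-Carlo draws for the stereology
limits; 100-repetition resampling experiments at n ∈ {10, …, 150} (×200
outer runs for the type-I error check); 100 seeded noisy series for
kinetics recovery. These sizes were chosen so each study's Monte-Carlo
error is comfortably inside the tolerance it is checked against.

## Known limitations

- Islets spanning section boundaries are double-counted unless
  `deduplicate_islets()` is applied; merged neighbors are not split (no 3D
  watershed).
- The circle-equivalent radius inherits the near-circular cross-section
  assumption; elongated islets are summarized by their hull anyway.
- Exclusion thresholds from a pooled self-reference shift slightly with
  the sample composition; supply a fixed reference population for strict
  cross-sample constancy.
- The adaptive-threshold block size (51 px) matters for nerve-positive
  calls and has no canonical value; results should be reported alongside
  the parameter set used, as the analysis scripts do.
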