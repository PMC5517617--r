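# voxislet

Automated volumetric histology of the endocrine pancreas: islet
segmentation and morphometry in cleared-tissue 3D fluorescence volumes,
peri-islet innervation scoring, the simulation studies that quantify the
statistical and stereological advantages of volumetric over section-based
measurement, and first-order tissue-clearing kinetics.

## Who this is for

Labs imaging cleared (hydrogel-embedded, optically transparent) pancreas —
or any organ with roughly spherical bright structures — who need
population-wide, unbiased quantification instead of manual measurement of a
few structures on a few sections. The package also serves as a simulation
bench: it ships a seeded synthetic-volume generator with exact ground
truth, so every pipeline stage is testable without external imaging data.

## What it computes

**Detection.** A two-channel volume (endocrine/insulin channel +
neural-crest/nerve channel) is normalized, maximum-intensity projected into
150 µm sections, segmented per section with Otsu's method (erosion/dilation
cleanup, ≥ 5 px regions), and each candidate is re-thresholded at full
local resolution in a 20 px-padded crop. The islet radius is the
circle-equivalent of the convex-hull area:

    r = sqrt(hull_area_px / π) · pixel_size   [µm]

**Innervation.** Each islet's neighborhood — its convex hull offset
outward by 2 px (10 µm), interior included — is scored as

    interaction_score = positive nerve px in neighborhood / islet area_px

with nerve positives from a local-mean adaptive threshold eroded by 1 px.
Records more than 3 standard deviations above a reference mean in
positive-pixel fraction or crop entropy are flagged as artifacts.

**Section-bias simulations.** Resampling power experiments (n islets with
replacement, 100 repetitions, two-tailed unpaired t-test) and a virtual
2D-vs-3D comparison: islets detected on optical sections of thickness 5-110
µm are re-measured in a z-extended 3D context, classified (10 µm size
threshold, 10 % tolerance: false negatives, false positives, within
tolerance, under/over-estimates), and summarized by the underestimation
factor (r3D − r2D)/r3D. A geometric Monte Carlo anchors the thin-section
limit at the chord average π/4 ≈ 0.785.

**Clearing kinetics.** UV-absorbance time series are fitted with
y = Y_max(1 − e^(−kt)); rates are normalized to a reference formulation.
Staining quality is quantified as mean cellular signal over extracellular
background after size/roundness filtering.

## Worked example

```r
library(voxislet)

cfg <- synth_config(volume_shape = c(220, 220, 24), n_islets = 6,
                    radius_distribution = list(name = "uniform",
                                               min_um = 20, max_um = 45),
                    min_center_separation = 40,
                    innervation_range = c(0.2, 0.9),
                    n_filaments = 0, background_noise_sd = 0,
                    z_contain = FALSE, xy_separation = TRUE, seed = 601)
sim <- generate_islet_volume(cfg)

pop <- detect_islets(sim$islet)
pop <- score_population(pop, sim$nerve)
print(pop)
#> <islet_population> synthetic: 6 records (6 retained)
#>   radius_um: median 33.4, range [29.9, 44.0]

head(as.data.frame(pop)[, c("islet_id", "radius_um", "area_px",
                            "interaction_score")])
#>   islet_id radius_um area_px interaction_score
#> 1        1  34.08564     146        0.54109589
#> 2        2  32.77645     135        0.91111111
#> 3        3  43.97423     243        0.87242798
#> 4        4  32.77645     135        0.54814815
#> 5        5  33.96871     145        0.16551724
#> 6        6  29.85411     112        0.09821429

round(sim$truth$islet_radii, 1)
#> [1] 44.2 34.0 33.7 33.0 32.1 29.6
```

All six generated islets are recovered, every detected radius is within a
few percent of its ground-truth value (e.g. 44.0 vs 44.2 µm), and the
interaction scores track each islet's drawn shell-innervation fraction.
The kinetics module works the same way:

```r
fit <- fit_clearing_rate(generate_clearing_series(1, 0.4, seq(0, 72, 2),
                                                  noise_sd = 0.03, seed = 501))
ref <- fit_clearing_rate(generate_clearing_series(1, 0.02, seq(0, 72, 2),
                                                  noise_sd = 0.03, seed = 503))
normalize_rate(fit, ref)
#> <kinetics_fit> y_max = 1.007, k = 0.3974 /h (SSE 0.0179), normalized rate 16.9
```

## The analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
narrative script over the package functions, writing tidy tables under
`results/` (bulk regenerable data such as TIFF stacks go to `scratch/`):

1. `01_simulate_volumes.R` — two developmental-stage volumes + ground truth
2. `02_detect_islets.R` — detection, accuracy vs truth, population CSVs
3. `03_score_innervation.R` — innervation scoring, artifact exclusion,
   stage contrast
4. `04_section_bias.R` — power curves; Monte-Carlo and image-pipeline
   section-bias sweeps; largest-20 comparison
5. `05_clearing_kinetics.R` — gel-formulation clearing rates, staining
   signal-over-background, protein-loss normalization

Run them in order from the repository root: `Rscript analysis/01_….R`.

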