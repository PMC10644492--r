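---
title: "Methods: quantifying spike architecture from scanner images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spike architecture from scanner images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikescan)
```

## The problem

Two-ranked unilateral grass inflorescences — perennial ryegrass spikes being
the canonical case — are flat enough that a flatbed scan captures their
architecture essentially without loss. `spikescan` turns such 8-bit RGB scans
(spikes on a dark, low-reflectance background) into per-spike and per-spikelet
descriptor tables: spike counts, four length estimates, spikelet counts and
ellipse fits, geometric and elliptical-Fourier shape descriptors, a
77-descriptor colour battery across RGB/HSV/CIELAB, and latent-trait
utilities. Because deposited field scans are large and external, the package
carries a synthetic scene generator with exact ground truth; every stage is
validated against that truth at desk scale.

## Spike segmentation

Foreground is separated from the background either by a manual threshold on
one RGB channel (default: red channel, strict `> 20`, the operating point that
minimised the count error on 600-dpi scans over black velvet), or by Otsu's
histogram threshold on the Rec. 601 luminance, scaled by a factor (default
0.29). On dark backgrounds the plain Otsu cut is too stringent — it sits far
above the background mode and clips into the spikes — hence the scaling.

Two numerical choices are fixed so results are reproducible:

* **Otsu tie-break.** When the between-class variance is flat across an empty
  gap between histogram modes (common in clean images), every threshold in the
  gap is a maximizer. We return the rounded midpoint of the maximizing set;
  taking the first maximizer would sit at the edge of the background mode and
  defeat the scaled variant.
* **Connectivity and enumeration.** Components are 8-connected, filtered at
  `min_area` (default 2000 px at full resolution, scaled by the square of any
  image rescale factor), and numbered left-to-right by bounding-box left edge
  (ties by top edge), matching how spikes are laid on a scanner bed.

Crops are padded by 10 px (morphology downstream needs background on all
sides) and carried in RGB, HSV and CIELAB (D65). Channel scales are fixed:
H in [0, 360) degrees, S and V on 0..255, L* on [0, 100], a*/b* signed.

## Spike length

Four estimators are provided:

* **ellipse** — full major-axis length (twice the semi-major axis) of the
  ellipse sharing the mask's normalized second central moments;
* **convex_hull** — the same rule on the rasterized filled convex hull;
* **skeleton** — Gaussian blur (`blur_sigma`, default 2 px), re-binarize at
  0.5, Zhang–Suen parallel thinning;
* **medial_axis** — same blur, then distance-ordered homotopic thinning:
  pixels are peeled in order of increasing Euclidean distance to the
  background, in four checkerboard subfields, deleting only simple
  (Hilditch test), non-end pixels, with a final sequential sweep. The result
  is a one-pixel skeleton centred on the distance-transform ridge. The two
  thinning methods differ only in the thinning operator.

For the thinning methods the length is the longest tip-to-tip geodesic on the
skeleton pixel graph after pruning leaf branches shorter than `prune_px`
(default 15 px — spikelet-induced spurs). Two practical details matter:

* **Digitization bias.** Summing 1/√2 step weights along a pixel path
  overestimates smooth curves by up to ~8% at orientations between the grid
  axes. `spk_length()` therefore measures the geodesic by chords over every
  15th path pixel (≈ the serration wavelength of a spike outline), which also
  averages out the small ridge meander that boundary serrations induce.
  `skeleton_path_length()` keeps the plain weighted-step definition
  (99 for a 100-px horizontal run, 99√2 for a perfect diagonal).
* **Holes and degenerate blobs.** Interior holes pinched off by the blur would
  survive homotopic thinning as loops and break the tip-to-tip path, so holes
  are filled before thinning (spike masks are solid objects). If parallel
  thinning annihilates a small compact blob outright — Zhang–Suen does this to
  disks — the blob's distance-transform maximum is returned as a one-pixel
  skeleton. The digital medial axis of a disk is a star of ridge arms to the
  octagonal corners rather than the ideal centre point; the geodesic is then
  bounded by the diameter.

On synthetic spikes the moment-based estimators are accurate for straight
spikes and collapse toward the chord for curved ones, while both thinning
estimators stay within 5% of the true arc length on semicircles — the
qualitative accuracy ordering reported for real scans (medial axis ≈ skeleton
> ellipse > convex hull on curved material).

Scale equivariance holds to 2% for the moment-based estimators; the thinning
estimators re-digitize the serrated boundary when the image is rescaled and
hold it only to ~5% at 0.8×.

## Spikelet detection

`spikelet_segm()` composes four stages on a padded spike mask:

1. **Cleaning** (`preprocess_mask`): the mask is down-scaled to 10% (nearest
   neighbour), eroded and opened with a cross-shaped 3×3 kernel (one
   iteration each), and scaled back. This strips the thin rachis and leaves
   the spikelet bodies as separate blobs. The upscale is bilinear with
   re-binarization at 0.5: a blocky nearest-neighbour upscale leaves corner
   plateaus in the distance transform that become spurious peak markers.
2. **Distance transform** (`distance_map`): exact Euclidean distance to the
   nearest background pixel.
3. **Markers** (`find_markers`): 8-neighbourhood local maxima, then greedy
   non-maximum suppression (higher peak wins, ties broken by row/col order)
   enforcing a pairwise separation of `min_distance` (default 25 px; on real
   scans 25–40 px gave under two misdetections per spike).
4. **Watershed** (`watershed_split`): seeded region growing on the distance
   map restricted to the mask (EBImage's `propagate`), flooding the negated
   distance relief from the markers. Every foreground pixel receives exactly
   one label and the label count equals the marker count; unreachable
   foreground patches are assigned to the nearest marker.

Each region then gets a moment-ellipse fit: area, semi-axes, major-axis
length and the orientation of the major axis in the image frame (origin at
the top-left corner, x rightwards, y downwards), degrees on [0, 180).
Regions under 5 px are flagged degenerate. An optional size filter
(`area_filter`, default off; `"auto"` uses median/4 .. 4×median) removes
misdetections by area. A spike whose mask vanishes during cleaning (e.g. a
bare rachis) is reported as zero spikelets with a warning.

`min_distance_sweep()` reruns the detector over a grid of minimum distances
against known counts, reporting the count RMSE (and the SD of the absolute
per-spike error) at each value — the tool for choosing `min_distance` for a
new image set.

## Shape descriptors

`region_geometry()` reports the classic region properties: area (pixel
count), moment-ellipse eccentricity and axis lengths, equivalent diameter,
extent (area over bounding box), solidity (area over rasterized filled hull,
hence ≤ 1), maximum/minimum Feret diameters (hull vertex distances and
rotating-calipers width), and perimeter as the weighted boundary chain
length (steps of 1 and √2).

`extract_contour()` fills interior holes and traces the outer boundary as a
closed (x, y) chain, oriented counter-clockwise in the y-down frame.
`efd_coefficients()` computes elliptical Fourier coefficients
a_n, b_n, c_n, d_n by the closed-form chain integrals for a polygonal contour
under arc-length parameterization; A0/C0 are the arc-length centroid.
`normalize_efd()` removes size (first-harmonic semi-major magnitude),
rotation (first-harmonic major axis to the x-axis) and starting point; a
residual joint ambiguity — advancing the start by half a period together with
a half-turn rotation, which flips every even harmonic — is pinned by making
the dominant even-harmonic coefficient positive. Normalized coefficients are
invariant to rotation and scaling of the input to ~1e-15.

Harmonic power is (a²+b²+c²+d²)/2; `harmonics_for_power()` returns the
smallest harmonic count whose cumulative power fraction exceeds a threshold
(default 0.9999), the "optimal" harmonic number carried into the descriptor
tables. One subtlety: under arc-length parameterization only a *circle* is
exactly single-harmonic; an eccentric ellipse has genuine higher-harmonic
power (a 40/30 ellipse concentrates 99.88% in harmonic 1, reaching 0.9999
only at n = 3). Tests therefore use a circle for the n* = 1 check.
`reconstruct_contour()` evaluates the truncated series;
`reconstruction_error()` (mean point-to-polygon distance) is non-increasing
in the harmonic count. `efd_symmetry_split()` partitions power into the
symmetric (b, c) and asymmetric (a, d) blocks.

## Colour descriptors

`channel_percentiles()` summarises the foreground pixel distribution of the
nine channels R, G, B, H, S, V, L*, a*, b*. The canonical record has exactly
77 fields: the seven non-chromaticity channels × {min, max, mean, sd, p5,
p25, p50, p75, p95} plus a*, b* × {mean, sd, p5..p95}. The extended block
appends per-channel CV (sd/mean) and QCV — the quartile coefficient of
dispersion (p75−p25)/(p75+p25) — and the full battery over the strictly
negative / strictly positive subsets of a* and b* with their pixel
fractions. Conventions fixed for bit-reproducibility: population SD
(divide by n), percentiles by linear interpolation between order statistics
(R type 7), CV undefined (NA) at zero mean, QCV at zero p25+p75.

## Latent traits and feature filtering

`pca_project()` centers and scales the descriptor table, takes the top-k
principal components, fixes each component's sign (largest-magnitude loading
positive, making the projection invariant to column order) and min-max
standardizes each score to [0, 1]. `mean_pairwise_ed()` returns the mean ±
SD of all pairwise Euclidean distances — the separability measure used to
compare descriptor sets. `feature_filter()` applies the preprocessing used
before model fitting: rows with curvature above mean + 5.5 SD dropped,
near-zero-variance columns dropped (fewer than two distinct values or
variance below 1e-8 after unit scaling), one member of each |r| > 0.85 pair
dropped (the one with the larger mean absolute correlation, via
`caret::findCorrelation`), survivors centered and scaled. The operation is
idempotent. The curvature proxy, `curvature_index()`, is medial-axis length
over moment-ellipse length minus one.

## The synthetic scene generator

A scene is a dark noisy background (level 10 ± 3 on the 8-bit scale — black
velvet under a scanner lid — safely below the default red threshold of 20)
with spikes laid side by side, disjoint by construction, at seeded random
horizontal slack and vertical offsets. A spike is a parametric centerline
(straight or circular arc, so the true arc length is analytic) carrying a
rachis band and alternately attached rotated ellipses; spike channel values
are floored at 40 so the stated background/foreground margin always holds.
Rendering is fully deterministic given spec and seed.

Two morphotypes are exercised:

* the default **spreading** morph (rachis 11 px, spikelet semi-axes 40×30 px,
  attach angle 35°, lateral offset 1.0 × semi-minor, spacing 50 px): large
  distinct spikelets that touch only the rachis. Its geometry was chosen from
  feasibility constraints of the detection pipeline itself — the spikelet
  minor diameter must span at least five cells at the 10% morphology scale to
  survive erosion + opening, consecutive ellipses must not touch each other
  (else the distance ridge bridges and the peak markers double), and ridge
  half-length must stay under `min_distance`;
* the **appressed** morph (`appressed_spike_spec()`: rachis 21 px, spikelet
  semi-axes 18×12 px, spacing 30 px, offset 0.75): many small spikelets
  appressed against a broad rachis, a smooth serrated band. This is the
  morph on which centerline length estimation is meaningful — on the
  spreading morph the skeleton would track the meander between alternating
  blobs rather than the rachis.

Spikelet size *and rachis width* taper along the rachis as (1−u²)^taper
(floor 0.3). Real spikes thin toward the tip; the exponent also controls the
simulated mass profile, and for the appressed morph (taper 0.35) the mixture
of the rachis profile (∝ f) and the spikelet profile (∝ f²) is close to the
semicircular density for which the moment-ellipse estimator is exactly
calibrated — the closed-form variance of a density (1−u²)^p on [−1, 1] gives
an estimate factor between +4% (p = 0.35) and −5% (p = 0.7), and the mixture
lands near zero. This is why all four estimators agree within 5% on straight
appressed spikes.

What the generator does **not** emulate: awns, overlapping spikes, specular
highlights, shadows, within-spike colour gradients and debris. Passing tests
therefore demonstrate correctness of the algorithms under the stated
geometric and photometric model, not segmentation robustness on arbitrary
field material; on real scans the threshold and minimum-distance sweeps are
the tools for adapting the operating points.

Colour-recipe helpers (`spike_color_recipes()`, `sample_recipe_spike()`)
produce three recipes with near-identical mean colour but different
distributional signatures (within-spike jitter, rachis/spikelet tone
contrast) and per-spike base-colour variation that swamps the recipe mean
differences — the configuration under which mean-RGB summaries overlap but
the full 77-descriptor battery still separates the recipes on standardized
principal components.

## Batch driver and reproducibility

`run_batch()` processes a directory of images into one CSV row per spike and
per spikelet (stable column order, UTF-8, 6 significant digits), an
annotated JSON run log, with per-image failures logged and skipped.
Reruns with the same config and seed are byte-identical; wall-clock timings
are therefore kept in `spk_length()` results and the run log, never in the
descriptor CSVs. `sweep_segmentation()` and `sweep_spikelets()` are the two
operating-point sweep tools. A thin command-line wrapper lives at
`inst/cli/spikescan.R` (subcommands `run`, `sweep-seg`, `sweep-spikelets`,
`simulate`).

## Problem sizes used in the tests

The packaged checks run at desk scale: scenes up to ~800×1700 px with 1–10
spikes, 20 seeded scenes for count recovery, 20 semicircular spikes
(arc lengths 450–640 px) for the length ranking, 50 spikes with 5–15
spikelets for spikelet recovery, 1000 random vectors for the descriptor
invariances, and 20 replicates of 60 spikes for the colour-separability
comparison. These sizes were chosen so the full suite exercises every claim
in minutes on a single CPU.

## Known limitations

* Thresholding assumes a dark, uniform background; no other background model.
* Overlapping spikes are not split; on real material they surface as
  outliers in length or Fourier descriptors.
* The spikelet detector requires `min_distance` matched to the spikelet
  scale; strongly curved spikes with tightly packed spikelets can merge
  neighbouring bodies at the 10% morphology scale.
* Pixel units throughout; no px→mm calibration.
* The thinning length estimators carry residual digitization effects of a
  few percent that do not vanish under mask rescaling.
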