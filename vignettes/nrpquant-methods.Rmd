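---
title: "Quantifying membrane redox permanganometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane redox permanganometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpquant)
```

## The assay and what the package computes

Nitrocellulose redox permanganometry (NRP) measures the total reductive
(antioxidant) capacity of a sample by letting it reduce KMnO4 on a
nitrocellulose membrane: the reduced manganese precipitates as brown MnO2 in
the membrane, so spot darkness encodes how much oxidant the sample could
reduce. HistoNRP extends this to tissue slices printed onto the membrane
with their anatomy preserved, yielding a two-dimensional map of reductive
capacity.

`nrpquant` implements everything downstream of the digitized membrane:

1. **Image import and the reductive scale.** Scanners record luminance —
   dark deposits are *low* values. All analysis happens after inversion to
   *reductive intensity* `1 - v`, so larger means more reduction
   (`to_reductive_scale()`). The working scale is floating point `[0, 1]`;
   8/16-bit integer codes exist only at file boundaries, which makes the
   math independent of the digitization device. Pixels are indexed
   `(row, col)`, 1-based, origin top-left; dorsoventral profiles run along
   increasing row.
2. **Spot densitometry.** Each 1-ul dot is quantified as a
   background-corrected integrated density.
3. **Calibration and validation.** Graded reducing-agent series
   (0.01–0.1 M in the reference design) are fitted by ordinary least
   squares and judged by bioanalytical accuracy/precision/linearity rules.
4. **Ratiometric protein normalization** for tissue homogenates, gated by a
   dispersion-justification rule.
5. **Bilateral spatial analysis** of slice prints: midline estimation,
   sagittal mirroring, sum/difference maps, line profiles, and per-region
   intensity-distribution comparison ranked by distance to a trauma site.
6. **Phantom generation**: synthetic membranes with exact ground truth, so
   every stage above is testable end to end without laboratory data.

## Integrated density

For a circular region of interest (ROI) with center $c$ and radius $r$, the
integrated density is

$$\mathrm{ID} = \sum_{p:\,\|p-c\|\le r}\bigl(I(p) - b\bigr),$$

where $b$ is the per-pixel background estimate. Disk membership uses pixel
centers with the boundary included, so the pixel count is deterministic.
The default background is the *median* intensity over an annulus spanning
1.2–1.8 ROI radii: the median resists bleed from neighboring spots, and the
annulus needs no user-drawn baseline. Negative IDs are possible for spots
dimmer than their surround and are flagged rather than clipped. Adding a
global constant to the image leaves the annulus-corrected ID unchanged;
scaling the image scales it linearly — both properties are tested.

A lane-profile mode (`extract_lane_profile()`,
`subtract_profile_baseline()`, `integrate_profile_peaks()`) mirrors the
classic gel-densitometry workflow: a rectangular lane is collapsed to a 1-D
mean profile, a piecewise-linear baseline is anchored at the local minima
flanking each peak (minimum prominence 5% of the profile range by default —
profile-analysis conventions give no canonical threshold, so it is
configurable), and peak areas are the sums of the corrected values. The
baseline is an automated stand-in for the manual baseline drawing of
interactive tools and is labeled as such in outputs. Disk/annulus and lane
quantification agree within 5% on clean phantoms (tested); disk/annulus is
the default because dots are isolated and the method is parameter-free.

Spot ROIs come either from a known pipetting grid (nodes refined to local
intensity centroids — the robust path) or from scale-normalized
Laplacian-of-Gaussian blob detection when no layout is known.

## Calibration and validation

Calibration regresses integrated density on nominal concentration over all
replicates (unweighted OLS by default; `1/x^2` weighting is available but
the assay's validated range shows no strong heteroscedasticity in the
phantom regime). Per level, the report computes

* **accuracy** — back-calculated concentration of the level mean over
  nominal, x100; pass requires every level within +-15%, relaxed to +-20%
  at the lowest level (the LLOQ), following standard bioanalytical
  method-validation guidance;
* **precision** — replicate CV (`100 * sd / mean`, n−1 denominator, a
  material choice at 5–6 replicates); pass at <= 15% (20% at the LLOQ);
* **linearity** — pass at R² >= 0.98. No canonical cutoff exists for this
  verdict, so it is explicit and configurable.

`compare_methods()` provides the method-against-method regression (e.g.
membrane readout vs. direct electrode redox potential of the same graded
samples), reporting R² and the two-sided p value for zero slope.
`compare_groups()` is a two-sided Wilcoxon rank-sum test; for combined
n <= 20 the null distribution of the rank sum is enumerated exactly by
dynamic programming over midranks (exact even under ties), otherwise a
tie-corrected normal approximation with continuity correction is used, and
the method used is reported.

## Ratiometric protein normalization

Equal volumes of tissue homogenate carry unequal protein, so tissue NRP
values are corrected as
$\mathrm{corrected}_i = \mathrm{density}_i \cdot p_{\mathrm{ref}} / p_i$,
which keeps values on the original integrated-density scale and leaves the
reference-matched sample untouched. Correction is only *justified* for
samples whose protein deviates from the representative value by strictly
less than 50% (the boundary itself fails). The representative sample
defaults to the batch **median** — the notion of a "representative sample"
is otherwise underdetermined, and the median is robust; a named sample or
explicit value can be substituted and the choice is recorded in output.
Because the ratio assumes signal linear in protein, the output carries a
density-vs-protein regression audit over the justified samples.

## Bilateral spatial analysis

The medial line is ideally drawn by the analyst; `estimate_midline()`
automates it by maximizing the Pearson correlation between the left block
and the mirrored right block over their overlap (ties toward the smaller
column; a manual midline always wins). The mirror axis passes through the
*center* of the midline column, `col' = 2m - col`, and the midline column
belongs to neither side — this convention makes mirroring an exact
involution on the integer grid, so a symmetric image produces a difference
map that is identically zero (tested as the "no false asymmetry" null).

`mirror_pair()` indexes both hemifields by the offset from the midline, so
homologous pixels share coordinates; `bilateral_maps()` forms the pixel
sum and difference; `line_profile()` reads paired dorsoventral profiles.
`compare_region()` samples an ROI (drawn once, on the ipsilateral side —
contralateral sampling is defined by the mirror map, not by independently
drawn ROIs) on both fields and reports the **oxidative increment**
`contra_mean - ipsi_mean`, positive where the lesioned side lost reductive
capacity, plus the Euclidean centroid-to-trauma distance in pixels.
`rank_regions()` sorts by that distance (alphabetical tie-break) and
reports Spearman's rho between distance and increment.

Density summaries use a Gaussian kernel with Silverman's bandwidth on a
shared 256-point grid. The grid spans the pooled value range extended by 6
bandwidths and each curve is trapezoid-renormalized: a grid clipped to the
data range cannot integrate a Gaussian KDE to 1, and the extension keeps
the discretized curve a proper density to within 1e-6 (tested). Zero-spread
inputs fall back to a minimal bandwidth rather than failing.

## The phantoms

The generators define the study conditions under which the pipeline is
validated; they are deterministic given a seed (byte-for-byte, and they
restore the caller's RNG state).

**Dot blot** (`make_dotblot()`): defaults mirror the reference series
design — 10 levels spanning 0.01–0.1 M, 6 replicates, linear response
(slope 8 intensity per mol/L keeps the top level near 0.8, safely inside
`[0, 1]` with noise), 5% multiplicative lognormal replicate CV, additive
Gaussian pixel noise (sd 0.01), and a faint tilted background plane
(0.05 + 1e-4/px). Spots are flat disks with a 2-px Gaussian-smoothed rim so
pixel areas are stable against aliasing; dots of a 1-ul pipette have no
documented profile, so the profile is a modeling choice. The truth table
records each spot's exact noiseless integrated density over the measurement
disk (spot radius + 3 px, covering the rim), making the zero-noise
ground-truth check exact to 1e-6. A saturating response
$A_{\max}(1-e^{-kc})$ exists to exercise validation-failure reporting; the
true near-saturation dose-response shape of MnO2 deposition is
uncharacterized, so this option is a stress test, not a claim. Optional
per-spot loading factors emulate unequal protein loading for the
normalization tests.

**Oxidation pair** (`make_oxidation_pair()`): isoconcentrated aliquot
pairs (0.05 M by default, six pairs) with a fraction `f` of reductive
capacity destroyed in the treated arm — the phantom analogue of physically
oxidizing half of each aliquot.

**Brain print** (`make_brain_phantom()`): a mirror-symmetric synthetic
slice (elliptical tissue plus mirrored internal structures) with a radial
multiplicative suppression $w(p) = 1 - \delta e^{-\|p-c\|^2/2\sigma_l^2}$
applied to one side only (defaults: depth 0.3, sigma 30 px), five circular
ROIs at graded distances from the trauma site placed in uniform-base tissue
so the expected increment decreases strictly with distance, and additive
pixel noise (sd 0.01). The closed-form increment of an ROI —
$\mathrm{mean}_\mathrm{ROI}\,[\,\mathrm{base}\cdot\delta\,
e^{-\|p-c\|^2/2\sigma_l^2}]$ — is checked against the pipeline output.

What the phantoms do **not** emulate: deposition chemistry and diffusion of
the slice print, optical vignetting or scanner-specific response curves,
spatially correlated membrane texture, touching or irregular spots, and
anatomically realistic parcellation. Passing phantom tests therefore
demonstrates the correctness of the *quantification*, not robustness to
every artifact of real membranes.

## Numerical choices and edge cases

* Degenerate calibration input (constant response) reports slope 0 and
  R² = 0 rather than propagating unstable least-squares output;
  back-calculation through a zero slope is refused.
* A flat lane profile yields a baseline equal to itself and all-zero
  corrected values — not an error.
* Uniform images make midline correlation undefined; the estimator asks for
  a manual midline instead of guessing.
* Annuli clipped by the image edge use their in-bounds portion and flag
  `partial_annulus`; ROIs under 10 px flag `small_roi`; spots dimmer than
  background flag `below_background`.
* All generator output is clipped to `[0, 1]` and clipping is flagged.

## Problem sizes

The test-suite and acceptance computations use the defaults above: 60-spot
calibration membranes (about 250 x 150 px), 200 repeated series for the
slope-bias estimate, 100 repeats per arm for the oxidation-pair power and
type-I rates, and 220 x 241 px brain phantoms — sizes at which every
quantity stabilizes well inside its acceptance band while the full suite
runs in well under a minute on a laptop.

## Worked example

```{r example, eval = FALSE}
ph <- make_dotblot(seed = 1)
rois <- detect_spots(ph$image, grid = ph$grid)
meas <- measure_spots(ph$image, rois)
meas$nominal <- ph$truth$nominal[match(meas$label, ph$truth$label)]
report <- validate_method(calibration_series(meas))
report
glance(report)
autoplot(report)

bp <- make_brain_phantom(seed = 1)
bmap <- bilateral_maps(mirror_pair(bp$image, bp$midline_col, "right"))
ranked <- rank_regions(compare_regions(bmap, bp$rois, bp$trauma))
attr(ranked, "spearman_rho")
plot_region_densities(ranked)
```
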