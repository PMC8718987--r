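# nrpquant

Digital quantification for **nitrocellulose redox permanganometry (NRP)**
and its spatial extension **HistoNRP**.

NRP is a dot-blot assay of total reductive (antioxidant) capacity: a
microliter of sample is spotted on nitrocellulose, the membrane is dipped in
KMnO4, and the sample's reducing power deposits brown MnO2 in place — spot
darkness encodes reductive capacity. HistoNRP prints a whole tissue slice
onto the membrane with anatomy preserved, turning the same chemistry into a
2-D map of reductive capacity. `nrpquant` covers everything after the
membrane is scanned, for lab scientists running either assay:

* **Image import and inversion** to a canonical *reductive-intensity* scale
  (`[0, 1]`, larger = more MnO2): `load_membrane()`, `to_reductive_scale()`.
* **Spot densitometry** — for each dot, the background-corrected integrated
  density `ID = Σ_disk (I(p) − b)` with `b` the median over a surrounding
  annulus; plus a gel-analyzer-style lane-profile mode:
  `detect_spots()`, `measure_spots()`, `extract_lane_profile()`.
* **Calibration and bioanalytical validation** of graded reducing-agent
  series: OLS fit, per-level accuracy (back-calculated / nominal × 100),
  replicate CV, and pass/fail verdicts at the ±15% / CV ≤ 15% rules (±20%
  at the LLOQ), linearity at R² ≥ 0.98: `fit_calibration()`,
  `validate_method()`; method-vs-method regression `compare_methods()` and
  an exact (tie-aware) Wilcoxon rank-sum `compare_groups()`.
* **Ratiometric protein normalization** for tissue homogenates,
  `corrected = density · p_ref / p`, gated by the rule that a sample's
  protein must deviate from the representative value by strictly less than
  50%: `check_dispersion()`, `ratiometric_correct()`.
* **Bilateral spatial analysis** of slice prints: midline estimation,
  sagittal mirroring (`col' = 2m − col`), pixel sum/difference maps,
  dorsoventral line profiles, and per-region ipsi-vs-contra comparison with
  the *oxidative increment* (`contra_mean − ipsi_mean`) ranked by distance
  to the trauma site: `estimate_midline()`, `mirror_pair()`,
  `bilateral_maps()`, `compare_regions()`, `rank_regions()`.
* **Synthetic phantoms with exact ground truth** so every stage is testable
  without wet-lab data: `make_dotblot()`, `make_oxidation_pair()`,
  `make_brain_phantom()`.

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures. A thin CLI (`inst/cli/nrp`)
wraps the same functions (`convert`, `quantify`, `validate`, `normalize`,
`spatial`, `simulate`) and writes a reproducibility manifest per run.

## Worked example

Simulate the standard graded-series membrane (10 levels of a reducing agent
over 0.01–0.1 M, 6 replicate spots each, 5% replicate CV), quantify it, and
validate the calibration:

```r
library(nrpquant)

ph   <- make_dotblot(seed = 1)
rois <- detect_spots(ph$image, grid = ph$grid)
meas <- measure_spots(ph$image, rois)
meas$nominal <- ph$truth$nominal[match(meas$label, ph$truth$label)]
validate_method(calibration_series(meas))
#> <validation_report>
#> <calibration_fit> density = -0.1139 + 659 * c   (R^2 = 0.9918, s = 1.75, n = 60)
#>    nominal n mean_density accuracy_percent cv_percent accuracy_ok cv_ok flags
#> 1     0.01 6        6.591           101.75      2.532        TRUE  TRUE
#> 2     0.02 6       13.580           103.89      2.896        TRUE  TRUE
#> ...
#> 10    0.10 6       66.660           101.32      5.845        TRUE  TRUE
#> accuracy: PASS   precision: PASS   linearity: PASS (R^2 >= 0.98)
```

The fitted slope, 659 intensity·px per mol/L, recovers the generator's true
noiseless density slope (653) within 1%; every level back-calculates to
98–104% of its nominal concentration with replicate CVs of 2.5–5.9%, so all
three validation verdicts pass.

Bilateral analysis of a lesioned brain print:

```r
bp     <- make_brain_phantom(seed = 1)   # lesion depth 0.3, sigma 30 px
bmap   <- bilateral_maps(mirror_pair(bp$image, bp$midline_col, "right"))
ranked <- rank_regions(compare_regions(bmap, bp$rois, bp$trauma))
dplyr::select(ranked, name, distance_px, oxidative_increment)
#>   name     distance_px oxidative_increment
#> 1 roi_d000           0             0.162
#> 2 roi_d020          20             0.132
#> 3 roi_d040          40             0.0668
#> 4 roi_d060          60             0.0232
#> 5 roi_d080          80             0.00635
attr(ranked, "spearman_rho")
#> [1] -1
```

The region at the trauma site lost the most reductive capacity (increment
0.162 of the ~0.55 baseline) and the loss decays with distance exactly
monotonically (Spearman ρ = −1), matching the phantom's radial lesion.

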