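# centrodyn

Quantification of mother/daughter centriole dynamics during hair-bundle
polarity acquisition in inner-ear hair cells, from 3D time-lapse
microscopy.

## The problem

Before a hair cell builds its mechanosensory hair bundle, its two
centrioles choreograph the bundle's future orientation on the apical
surface. Live imaging (GFP-centrin spots plus a cytoplasmic tdTomato
reporter, 0.216 µm pixels, 0.5 µm z-steps, one stack per 10 min) shows two
phases: a confined stage with the mother centriole (MC, future basal body
of the kinocilium) near the apical centre and the daughter centriole (DC)
moving around it (Phase I), then a DC-led directed migration to the
lateral periphery that the MC follows (Phase II). Emx2 expression reverses
the target side; nocodazole recalls the centrioles to the centre.

`centrodyn` is a tidyverse-style R implementation of that entire
quantification, driven by its own synthetic-data generator so every
estimator can be scored against ground truth:

* **simulation** — stochastic two-centriole dynamics on an apical disk
  (mean-reverting steps, per-frame caps at the observed speed bounds of
  0.5 µm/frame for the MC and 1.2 µm/frame for the DC), Emx2 axis flips,
  nocodazole recall, reporter kinetics, whole-cell drift, and rendering to
  calibrated two-channel 3D+t stacks with Poisson-Gaussian noise
  (`simulate_cell()`, `simulate_cohort()`, `render_image_series()`);
* **registration** — drift correction by phase correlation of maximum
  projections with DFT-upsampled subvoxel refinement, axial-profile z
  shifts, and track detrending against the cell centre
  (`estimate_shifts()`, `apply_shifts()`, `detrend_tracks()`);
* **tracking** — reporter-based cell masks, masked LoG spot detection
  with subvoxel refinement, minimal-displacement linking with gap
  closing, and MC/DC role assignment by mean apicality
  (`segment_cells()`, `detect_spots()`, `link_tracks()`,
  `assign_mc_dc()`);
* **trajectory metrics** — inter-centriole distances
  `d_xy = ||(Δx, Δy)||`, `d_z = |Δz|`; per-frame x-y speeds on
  centre-relative coordinates; time-averaged MSD with its scaling
  exponent α (α ≈ 1 Brownian, ≈ 2 directed); radial r and signed-axis s
  coordinates (`pair_distances()`, `frame_speeds()`, `msd_curve()`,
  `radial_series()`);
* **event detection** — retroactive Phase-II entry (window gain
  ≥ 1 µm over 1.5 hr with ≥ 60 % outward increments, then reaching
  0.6 R), late Phase II, direct-vs-reversal mode classification on the
  signed axis, reporter onset (background + 3σ sustained), reversal
  latency, and drug-induced peripheral loss (`detect_phase2_entry()`,
  `classify_mode()`, `detect_reporter_onset()`, `perturbation_events()`);
* **statistics** — pooled-variance Student t, uncorrected 2×2 chi-square
  χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), one-way ANOVA, and cohort
  reports with printed-style percentages (one decimal, half-up)
  (`ttest_two_sample()`, `chisq_2x2()`, `anova_oneway()`,
  `cohort_report()`).

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()`, `autoplot()` and `plot_trajectory()`.

## Worked example

```r
library(centrodyn)

cohort <- simulate_cohort(sim_params(), n = 10, seed = 101, n_frames = 250)
res <- analyze_cohort(cohort)
dplyr::select(res, cell_id, mode, phase2_entry, true_entry, latency_hr)
#> # A tibble: 10 × 5
#>    cell_id  mode     phase2_entry true_entry latency_hr
#>    <chr>    <chr>           <int>      <int>      <dbl>
#>  1 cell_001 direct             61         64      NA
#>  2 cell_002 direct             56         57      NA
#>  3 cell_003 reversal           65         67       9.67
#>  4 cell_004 reversal           60         61       9.83
#>  5 cell_005 direct             60         62      NA
#>  6 cell_006 direct             65         65      NA
#>  7 cell_007 direct             59         59      NA
#>  8 cell_008 reversal           59         59       9.5
#>  9 cell_009 reversal           56         57      15.5
#> 10 cell_010 reversal           57         58      10.8

ttest_two_sample(res$mean_d_xy_II, res$mean_d_xy_I)
#> <test_result> t_student: statistic = 33.94, df = 18, p = 9.034e-18
```

Each row is one simulated cell: `mode` is the detected trajectory class
(`direct` = the DC went straight to the medial side; `reversal` = it
established laterally first, then crossed), `phase2_entry` the detected
onset of directed migration (frames, 10 min each) against the generator's
scheduled `true_entry`, and `latency_hr` the time from reporter onset to
the DC's sustained medial excursion — the reported 10–12 hr observable.
The t-test confirms the planar inter-centriole distance is larger in
Phase II than Phase I across cells, the printed direction of effect.

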