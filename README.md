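# holotomo

Label-free phase-contrast tomography of plant-cell nuclei that rotate while
their cell dehydrates.

When an onion epidermal cell loses water, its turgor pressure drops, the
cytoskeletal constraints on the nucleus relax, and the nucleus starts to
roll about an axis lying in the image plane. A digital holographic
microscope watching the cell therefore collects, for free, a sequence of
quantitative phase maps (QPMs) of the same rigid nucleus seen from many
angles — exactly the input a tomographic reconstruction needs. The catch is
that the rolling angles are unknown. `holotomo` implements the full
computational chain that turns such a time-lapse into a 3D refractive-index
(RI) map of the nucleus and a quantitative report on its nucleolus:

1. **Holography** — off-axis hologram demodulation (`demodulate_offaxis()`),
   angular-spectrum refocusing (`propagate()`), and autofocus by maximizing
   the Tamura contrast coefficient √(σ/μ) (`tamura()`, `autofocus()`).
2. **Dehydration dynamics** — global image contrast Σ|∇²φ|
   (`global_contrast()`), a logistic fit L(t) = A + (B−A)/(1+e^{−k(t−t₀)})
   whose derivative peak marks plasmolysis (`fit_logistic()`,
   `detect_plasmolysis()`), and the post-plasmolysis protoplast/cell area
   trend (`area_ratio_trend()`).
3. **3D tracking** — mask centroids, projected area and in-plane orientation
   from second moments, axial position by Tamura refocusing
   (`track_nuclei()`).
4. **Rolling-angle recovery** (the core algorithm) — each frame is segmented
   with an elliptic mask (`segment_ellipse()`); the major axis stays fixed
   (the rotation axis) while the minor-axis length l_k traces
   l(β) = 2√(b²cos²β + c²sin²β). Inverting this curve gives the folded angle
   β_k ∈ [0°, 90°]; every extreme of l_k marks a passed 90° cell, so the
   monotone rolling angles θ_k follow by reflection and offsetting
   (`build_minor_axis_curve()`, `invert_angle()`, `unwrap_angles()`).
   Extrema that do not reach the global minimum/maximum are angularly
   indeterminate and those frames are excluded.
5. **Tomography** — filtered back-projection of the aligned phase profiles
   at the recovered non-uniform angles, Ram-Lak (or Hann) filtered, with
   n = n_bg + g·λ/2π (`fbp_reconstruct()`).
6. **Morphometry** — nucleus and nucleolus segmentation by RI interval,
   volumes, sphere-equivalent radii, principal axes, RI statistics, and dry
   mass m_d = (n̄ − n_w)·V/α with n_w = 1.334 and α = 0.2 µm³/pg
   (`nuclear_metrics()`, `report_table()`).

Because no experimental stacks are distributed, a first-class phantom module
renders analytic phase projections of a rotating two-ellipsoid nucleus
(nucleoplasm + denser nucleolus), optionally embedded in synthetic off-axis
holograms with noise (`phantom_spec()`, `make_phantom()`,
`synthesize_hologram()`). Every stage of the pipeline is validated against
these closed-form phantoms.

## Worked example

Simulate a 26-frame dehydration sequence of a rotating nucleus (semi-axes
11.72 × 7 × 3.5 µm, Δn = 0.022 over cytoplasm at 1.368, nucleolus +0.02)
spanning 300° with 0.03 rad phase noise, then run the full pipeline:

```r
library(holotomo)

cfg <- pipeline_config(
  output_dir = "run", pixel_size = 0.25,
  phantom = list(grid_shape = c(128, 128),
                 angle_schedule = schedule_uniform(26, 300),
                 noise_sigma_phase = 0.03))
sim <- simulate_phantom_dataset(cfg)
res <- run_pipeline(cfg, sim$stack_path)

glance(res$angles)
#> # A tibble: 1 × 5
#>   n_frames n_valid n_extrema n_local_extrema max_rolling_angle
#>      <int>   <int>     <int>           <int>             <dbl>
#> 1       26      26         3               0              299.
```

The three extrema of the minor-axis curve are all global here, so all 26
frames carry usable angles and the recovered rotation spans 299° of the
true 300°. The metrics record (`res$metrics`) reports:

```
nuclear volume 1698.3 um^3, equivalent radius 7.40 um
nuclear RI 1.3851, nucleolar RI 1.4085, volume ratio 2.77 %
nuclear dry mass 433.8 pg, nucleolar dry mass 17.51 pg
nucleolar volume 47.0 um^3   (ground truth 46.1 um^3)
```

The nucleolar RI mean sits ~0.023 above the nucleoplasm, its volume is
recovered within 2 %, and the nuclear mean RI is within 0.005 of the true
1.390; the nuclear volume is the least certain number (the segmentation
threshold rides on the smoothed reconstruction edge at 26 views). With 180
uniform views the interior RI is accurate to better than 0.002 —
see the methods vignette (`vignettes/rolling-nucleus-tomography.Rmd`) for
what the phantom does and does not establish about real data.

`autoplot()` methods exist for the fitted logistic, the minor-axis curve,
the angle series and the area trend; `plot_slice()` renders tomogram
cross-sections. A thin CLI wrapper lives at `inst/scripts/holotomo.R`
(`simulate` and `run` subcommands).

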