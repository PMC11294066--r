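# petmoco — data-driven head motion correction for brain PET

Head motion during a brain PET scan blurs the image, biases regional uptake
values, and misaligns the emission data with the CT attenuation map. In
short single-bed-position acquisitions (a few minutes on modern
high-sensitivity scanners) a substantial minority of patients move enough
to compromise quantification. petmoco implements a data-driven, frame-based
correction for this setting, for researchers who want a fully inspectable,
end-to-end testable counterpart to the vendor implementations of this
method family:

1. **Detection** — the centroid of distribution (COD), the mean
   TOF-estimated event position per 1 s bin, is tracked over the scan.
   Within the current motion-free stretch a running count-weighted mean is
   maintained and bin *b* is flagged when, on any axis,
   |c_b − c̄| / (s·√(1/n_b + 1/N)) exceeds the two-sided normal quantile at
   a Šidák-shared level (per-bin false-alarm rate α, default 0.01 — the
   detector's only knob). Two consecutive flags declare motion; frames
   shorter than 5 s are rejected.
2. **Estimation** — each motion-free frame (MFF) is reconstructed without
   attenuation correction and rigidly registered (6-DOF, joint-histogram
   mutual information, deterministic coarse-to-fine search) to the first
   frame, giving T(i); the first frame is assumed aligned with the CT.
3. **Correction** — the attenuation map is carried into each frame with
   T(i)⁻¹, each frame is reconstructed with attenuation-corrected OSEM
   (3 iterations × 10 subsets, 6 mm post-filter), pulled back to reference
   space with T(i), summed, and normalised by the retained duration.

The package ships a digital brain phantom (11 composite gray-matter
regions), a list-mode event simulator with known injected rigid motion, and
the evaluation layer used to quantify correction quality: cerebellum-
referenced SUV-ratio gray-matter masking, regional SUV means and percent
changes, per-region motion distances, and the small/large motion
classification based on a 5% frontal-lobe SUV change.

## Worked example

The standard validation study simulates a 180 s scan of the phantom with a
single step of 10 mm translation + 10° axial rotation at t = 60 s
(≈ 5,000 detected counts/s), runs the full pipeline, and quantifies both
the uncorrected (NMC) and corrected (HMC) images against a motion-free
reference simulated with the same random numbers:

```r
library(petmoco)
st <- run_validation_study(seed = 1)
glance(st)
#> # A tibble: 1 × 13
#>    seed n_events n_mffs rejected_s detected_motion_time_s nmc_mean_abs_error_pct
#>   <int>    <int>  <int>      <dbl>                  <dbl>                  <dbl>
#> 1     1   909366      2          0                     60                   14.4
#>   hmc_mean_abs_error_pct nmc_mean_error_pct hmc_mean_error_pct
#> 1                   1.64              -14.2              -1.63
#>   translation_error_mm rotation_error_deg frontal_change_pct motion_class
#> 1               0.0529             0.0986               5.16 large
```

Reading this: the detector found the injected step at exactly 60 s and cut
the scan into 2 usable frames with nothing rejected; registration recovered
the 10 mm / 10° step to 0.05 mm and 0.1°; the blurred, attenuation-
mismatched NMC image misses the motion-free regional SUV means by 14.4% on
average across the 11 gray-matter regions (mean signed error −14.2%), while
after correction the average error is 1.6%; and the frontal-lobe SUV rose
by 5.2% after correction, so the study is classified as large motion. The
per-region table is in `st$report` (here abbreviated):

```r
st$report
#> # A tibble: 11 × 6
#>    region      suv_mean_ref nmc_percent_error hmc_percent_error mean_hm_distance_mm max_hm_distance_mm
#>  1 amygdala         0.00224            -22.4             -4.90                 5.61                8.42
#>  3 cerebellum       0.00251            -13.1             -1.37                10.7                16.1
#>  4 frontal          0.00304             -5.98            -1.13                 3.33                5.00
#>  7 occipital        0.00335            -17.6             -0.880               13.4                20.2
#> 11 thalamus         0.00289             -4.64            -0.494                7.61               11.4
```

(The frontal lobe's small motion distance is real geometry: for this
combined step the rotation's tangential displacement largely cancels the
translation there.) Individual stages are ordinary functions that chain on
tibbles and volumes — `simulate_events()`, `compute_cod_trace()`,
`estimate_stat_noise()`, `detect_motion()`, `segment_mffs()`,
`bin_events()`, `osem()`, `mi_rigid_register()`, `apply_transform()`,
`run_hmc()`, `roi_suv_mean()`, `percent_change()`, `classify_motion()`,
`hm_distance()` — with `tidy()`/`glance()` methods and `autoplot()` for COD
traces and region reports.

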