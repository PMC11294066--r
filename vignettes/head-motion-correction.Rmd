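---
title: "Data-driven head motion correction for brain PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven head motion correction for brain PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

petmoco implements a data-driven, frame-based correction for rigid head
motion in short (minutes-long) single-bed-position brain PET acquisitions,
together with the simulation and evaluation machinery needed to exercise it
end to end without any external data. This vignette explains the models,
the tunable parameters and their defaults, what the synthetic data do and do
not emulate, and the numerical and design choices behind the implementation.

## The correction model

Head motion during a brain PET scan blurs the reconstructed image and
misaligns the emission data with the CT-derived attenuation map. The
correction assumes motion is *piecewise constant*: the head holds a pose,
occasionally jumps to a new one, and the scan can therefore be cut into
motion-free frames (MFFs) that are individually sharp. The pipeline has
three stages.

**Detection.** Every coincidence event carries a TOF-estimated annihilation
point. The centroid of distribution (COD) — the mean event position per 1 s
bin — is a low-dimensional surrogate for head pose: a rigid repositioning
shifts it, while counting statistics only jitter it with standard deviation
$s_a/\sqrt{n}$ along axis $a$, where $s_a$ is the per-event positional
spread and $n$ the events in the bin. The detector estimates $s_a$ robustly
(median absolute deviation over all events, scaled to an SD) and runs a
running-mean z-test: within the current frame it tracks the count-weighted
mean COD, and bin $b$ is flagged when on any axis

$$ \frac{|c_b - \bar c|}{s_a \sqrt{1/n_b + 1/N}} > z_{1-\alpha_\text{axis}/2}, $$

with $N$ the accumulated events of the frame and the per-axis level
$\alpha_\text{axis} = 1 - (1-\alpha)^{1/3}$ (Šidák sharing across the three
axes), so the per-bin any-axis false-alarm rate is exactly $\alpha$ under
the null. Motion is *declared* only when two consecutive bins are flagged —
single-bin count flukes are discarded — and the declared motion time is the
first flagged bin's start. A flagged-but-unconfirmed bin is withheld from
the running mean and folded back in if the next bin is quiet; after a
declaration the running statistics restart at the motion time. The only
knob is $\alpha$ (default 0.01). Frames shorter than 5 s are discarded and
counted as rejected data.

**Estimation.** Each MFF is reconstructed *without* attenuation correction
(attenuation-mismatch artifacts would otherwise contaminate the frames
differently) and rigidly registered to the first MFF, which is assumed
aligned with the CT. The estimate $T(i)$ maps reference-space points into
frame-$i$ space. The similarity metric is joint-histogram mutual
information; both images are Gaussian pre-smoothed (default SD 5 mm)
because the MI surface of noisy, non-converged frame reconstructions is
rugged enough to displace the rotation optimum by degrees. The search is
deterministic: an exhaustive coarse grid over 3D translations crossed with
axial rotations at a 4x-downsampled level, then Nelder–Mead over all six
parameters at each pyramid level up to full resolution.

**Correction.** For each frame the attenuation map is carried into frame
space with $T(i)^{-1}$, the frame is reconstructed with attenuation
correction (OSEM, 3 iterations x 10 subsets), pulled back to reference
space with $T(i)$ (trilinear), and the count-scale frame images are summed
and divided by the total retained duration. Count-scale summation makes the
corrected image equal the plain full-duration reconstruction in the
motionless limit. The uncorrected (NMC) image is a single reconstruction of
all events with the unmoved attenuation map.

## Reconstruction model

The scanner model is deliberately desk-scale: a stack of independent axial
slices, each viewed by 60 parallel-beam angles over 180 degrees with 64
radial bins of 3 mm. The projector is pixel-driven — each in-plane voxel
centre projects to a radial coordinate and its value is split linearly
between the two neighbouring bins, weighted by the in-plane voxel size so
that forward projection of a 1/mm attenuation map yields dimensionless line
integrals — and the back projector is the exact matrix transpose, which
keeps the EM update consistent. Attenuation enters as per-line survival
factors $e^{-\int \mu \, dl}$ multiplying the expected counts. The OSEM
update is the standard multiplicative step with interleaved balanced
subsets (angle $i$ to subset $i \bmod 10$), a uniform start inside the
field-of-view cylinder, zero-sensitivity voxels forced to zero and 0/0
ratios treated as zero. With one subset this is MLEM, and its Poisson
log-likelihood is nondecreasing at every iteration — asserted in the test
suite against an independently coded likelihood.

Every reconstruction ends with a 6 mm FWHM Gaussian post-filter, the usual
clinical practice. Besides controlling noise, the shared post-filter sets a
common nominal resolution: corrected frames are resampled once (trilinear)
on their way back to reference space, and without a common filter that
sub-voxel interpolation blur would dominate comparisons against
unresampled references.

## The synthetic phantom and event stream

The phantom is an ellipsoidal head on a 64 x 64 x 32 grid of 3 mm voxels: a
cortical shell partitioned into lobes, subcortical blobs, white matter, a
uniform soft-tissue attenuation map (0.0096/mm) inside the head, and an
integer label volume carrying 11 composite gray-matter regions (amygdala,
caudate, cerebellum, frontal, hippocampus, insula, occipital, parietal,
putamen, temporal, thalamus) plus white matter and background. Two uptake
profiles exist. The default `"fdg"` profile assigns realistic regional
contrast (striatum and occipital cortex hottest, cerebellum below cortex,
mesial temporal structures lowest among gray matter, mean GM:WM about 4:1).
A uniform profile (every gray-matter voxel at exactly the configured ratio)
is also available; note that with uniform gray matter the
cerebellum-referenced SUV-ratio mask at threshold 1.0 is degenerate — every
gray-matter voxel sits exactly at ratio 1 — which is one reason the
contrasted profile is the default. The subcortical structures are drawn
larger than anatomy (each composite region spans at least ~170 voxels):
at desk-scale count levels, ROI means over anatomically faithful tiny
structures would be statistically meaningless.

The simulator draws per-second Poisson event counts, samples annihilation
points from the activity image (uniform within the voxel), moves them by
the trajectory transform active at the event time, assigns a uniformly
random view angle and the nearest radial/slice bins from the true position,
thins events by the survival factor of the (moved) attenuation map along
that line, and records the true position plus isotropic Gaussian TOF blur
(default SD 12 mm, the positioning scale of a ~190 ps timing resolution).
`rate_cps` is the *emitted* rate: under the default phantom about one third
of emitted events survive attenuation thinning. Everything is driven by one
seed; the same seed reproduces the stream byte for byte.

What the simulation does *not* emulate: scatter, randoms, normalisation,
dead time, decay, continuous (intra-second) motion such as tremor, oblique
LORs, and TOF-weighted reconstruction (TOF enters only through event
positioning). Frame-based correction cannot address continuous motion by
construction, so passing tests here say nothing about tremor-like motion;
they demonstrate step-motion correction under idealised physics.

## The standard validation study

`run_validation_study()` fixes the package's reference experiment: a 180 s
scan of the default phantom with one step of 10 mm in-plane translation
plus 10 degrees axial rotation at t = 60 s, emitted at 15,000 cps — chosen
so the *detected* stream runs at about 5,000 counts/s, the rate such a
short clinical-style acquisition is quoted at. Quantification compares
regional SUV means (over the ground-truth labels) of the corrected and
uncorrected images against a motion-free reference reconstruction.

Two evaluation choices matter and are deliberate:

* **Common random numbers.** The motion-free reference stream uses the
  same seed as the moving stream, so the two share their Poisson draws and
  the shared counting noise cancels in percent errors. The reported errors
  therefore measure motion artifacts and correction fidelity, not counting
  noise. Independent references at these counts would bury a
  percent-level comparison under several percent of ROI-mean noise.
* **Ground-truth ROIs.** Regional means are taken over the phantom's label
  volume. The SUV-ratio gray-matter masking path (`gm_mask_from_suvr()`)
  is implemented and tested on constructed cases, but thresholding a noisy
  reconstruction selects upward-fluctuating voxels and would bias the
  reference's ROI means upward — an artifact of the simulation's count
  level, not of the method.

Under these conditions the uncorrected image typically misses the
motion-free regional means by 12–15% on average across the 11 regions,
while the corrected image lands within about 1.5–2%; the recovered
transform is accurate to a few hundredths of a millimetre and a few tenths
of a degree. These numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## Numerical choices and conventions

* World coordinates are in mm with the origin at the volume centre; voxel
  indices are 0-based in the resampling math. All transforms act on world
  points: $p \mapsto R\,(p - c) + c + t$ with intrinsic Z-Y-X Euler angles.
* Resampling is pull-back: output voxel centre $v$ receives the input value
  at $T(v)$; out-of-grid samples are zero. Nearest-neighbour resampling of
  an integer-voxel translation is an exact lattice shift.
* The SUV-ratio threshold is strict (`> 1.0`): boundary voxels exactly at
  the cerebellum mean are excluded, deterministically.
* The small/large motion classification uses `>=` at the 5% frontal-lobe
  change, so a change of exactly 5% counts as large.
* Per-minute motion-distance summaries split frames at minute boundaries
  and weight by the overlapping duration.
* Empty 1 s COD bins are bridged (no test is possible there) with a
  warning; traces shorter than 3 bins skip detection entirely.
* The detector's declared motion times restart its running statistics, so
  consecutive repositionings are handled independently; because declaration
  needs two flagged bins, the declared-motion rate under the null is of
  order $\alpha^2$, while the per-bin test itself is calibrated at
  $\alpha$.
* A single usable MFF degenerates gracefully to a plain
  attenuation-corrected reconstruction; no usable MFF at all is an error.

## Problem sizes

The shipped tests and the acceptance script run, on one CPU, with: 10,000
bin null traces (100 replicates) for detector calibration; a 32 x 32
single-slice disk for likelihood-monotonicity and convergence checks; 25
seeded frame pairs at ~105,000 counts/frame for registration recovery; and
3–5 seeds of the standard validation study. These sizes were chosen so the
whole suite completes in minutes while every Monte-Carlo interval quoted in
the tests retains its nominal coverage.

## Known limitations

* The per-slice parallel-beam geometry is a stand-in, not a scanner model;
  no numerical agreement with any vendor console is claimed.
* In-plane voxels must be square for the projector; the clinical
  1.20 x 1.20 x 1.45 mm grid is supported (square in-plane), arbitrary
  anisotropy in-plane is not.
* Motion between the CT and the first MFF is assumed absent, exactly as the
  correction assumes; a deliberate misalignment can be injected via
  `hmc_config(ct_misalignment = ...)` to demonstrate the resulting
  artifact, but no correction for it is attempted.
* Rotations about in-plane axes are supported by the registration and
  transform machinery, but the simulator's default motions are 4-DOF
  (in-plane translation + axial rotation + axial translation) so that the
  per-slice projection model remains consistent with the moved activity.
* Dynamic (kinetic) studies are out of scope: summation assumes a
  stationary tracer distribution over the scan.
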