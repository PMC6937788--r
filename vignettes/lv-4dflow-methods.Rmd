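---
title: "Regional LV 4D-flow analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional LV 4D-flow analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvflow)
```

## What the package computes

`lvflow` analyzes time-resolved, three-directionally encoded (4D-flow)
cardiac MRI velocity data of the left ventricle together with a
time-resolved binary segmentation of the LV blood pool on the same grid.
From these two inputs it derives, per subject:

* **Regional through-plane flow.** Each short-axis slice is assigned to
  one of three equal-length long-axis segments — base, mid-ventricle,
  apex — measured at end diastole from the center of the apical-most
  in-mask slice to the center of the basal-most one. Through-plane flow
  in a slice at a frame is the mean through-plane velocity over in-mask
  voxels times the in-mask cross-sectional area, converted to L/min;
  the regional curve is the unweighted mean of its member slices.
  Positive flow points from apex to base, so peak positive flow is
  systolic ejection and the magnitude of the most negative value is the
  diastolic peak.
* **Kinetic energy indexed to EDV.** Per frame, the in-mask sum of
  `1/2 * rho * V_vox * |v|^2` with blood density `rho = 1.06` g/cm³,
  averaged over frames and expressed in µJ; KEi_EDV divides by
  end-diastolic volume. KE is whole-LV only: a regional split of a
  velocity-squared quantity is dominated by the few fastest voxels and
  becomes noise-limited in slow-flow regions such as the apex.
* **Flow compartments.** Pathlines are emitted from every end-diastolic
  blood-pool voxel (optionally a regular subsample) and integrated with
  fixed-step classic RK4, forward to end systole and backward to the
  previous end systole, so the whole cycle is covered. Velocity is
  sampled trilinearly in space and linearly in cardiac phase with
  periodic wrap. A pathline that is outside the LV at the backward
  endpoint *entered* during diastole; one outside at the forward
  endpoint *leaves* during systole. Entered-and-leaves is direct flow,
  entered-only retained inflow, leaves-only delayed ejection flow,
  neither residual volume. Any wall crossing located in the
  mid-ventricular or apical region excludes the pathline; compartment
  percentages are volume fractions of the non-excluded pathlines and
  always sum to 100.
* **Global function.** Cavity volume by voxel counting per frame; ED/ES
  as the volume extremes (earliest frame on ties); EDV, ESV, SV, EF,
  and cardiac output `SV × HR / 1000`. Infarct size, when 17-segment
  transmurality scores (0–4) are supplied, is the mean score divided by
  four, as a percentage.
* **Cohort comparison.** For each of the 11 flow parameters (two peaks
  × three regions, KEi_EDV, four compartment percentages), an OLS model
  `outcome ~ group + age + sex + heart rate` with group coded AMI = 1
  and sex coded M = 1; the adjusted group difference is the group
  coefficient with a t-based CI. Demographics use Welch t-tests and a
  chi-squared test without continuity correction for sex; flow
  parameters are summarized as median ± IQR (type-7 linear-interpolation
  quartiles); associations use Spearman rank correlation (mid-rank
  Pearson rho; exact p for n ≤ 10 without ties, t approximation
  otherwise).

## Background phase-error correction

Phase-contrast velocity offsets are modelled per component as a
3rd-order 3-D polynomial — the 20 monomials `x^a y^b z^c`, `a+b+c ≤ 3` —
fitted by least squares to the *temporal-mean* velocity of static-tissue
voxels and subtracted from every frame. Fitting the temporal mean
encodes the assumption that the background error is time-constant, which
also guarantees the correction never alters temporal fluctuations.
Coordinates are normalized to `[-1, 1]` over the grid extent; in raw
millimetre coordinates the cubic design matrix is severely
ill-conditioned. The fit refuses rank-deficient static regions (e.g. a
single plane, which makes the cubic-in-one-axis terms collinear) and
reports the condition number.

No standard criterion exists for "static tissue", so the default rule —
a voxel is static when the temporal SD of its speed falls below the 30th
percentile of in-body voxels — is a package convention, exposed as
`sd_percentile`. Phantom validation bypasses the rule and uses the
known-truth exterior instead, separating the estimator's accuracy from
the mask heuristic.

## The synthetic phantoms and what they do (not) emulate

No public accession exists for the study data this kind of pipeline is
applied to, so every stage is validated against synthetic data with
closed-form truth.

**Deforming half-ellipsoid** (`ellipsoid_phantom()`): cavity with closed
apex at long-axis position 0 and open base at `L`, wall radius
`r_w(z,t) = R(t) sqrt(1 - ((L-z)/L)^2)`,
`R(t) = R0 (1 - alpha sin^2(pi t / T))`. Incompressibility gives the
axial velocity in closed form — uniform over each cross-section with
`v_z A = -dV_apical/dt` — and the radial velocity reduces to
`v_r = r R'(t)/R(t)`. Defaults `R0 = 2` cm, `L = 8` cm, `alpha = 0.2`,
20 frames, 1.25 mm isotropic spacing mirror a plausible adult LV (EDV
67 mL, EF 36%) at the high-resolution reconstruction scale; the first
half of the cycle is systolic and ED is the frame of maximum volume.
Noise, when requested, is added *after* the truth is recorded, so truth
always refers to the noiseless field.

On this phantom the voxel-counted volume agrees with `(2/3)πR²L` to
within 2% and every per-slice flow curve matches the analytic flux to
within 3% **of the phantom's peak flux**. The normalization matters: the
apical-most slices contain only a handful of voxels, where binary-mask
area voxelization fluctuates by tens of percent of those slices' own
tiny peaks (a Gauss-circle counting effect that no voxel-counting
implementation avoids at 1.25 mm), while their absolute errors remain
negligible against the phantom's flow scale.

**Plug-flow cylinder** (`plug_phantom()`): a static cylindrical cavity
with spatially uniform axial velocity — inflow displacement `d_in`
during the diastolic half-cycle, outflow `d_out` during the systolic
half. Transport is pure 1-D translation, so compartment truth follows
from interval overlaps: the top `d_in` of the cavity at ED entered
during diastole, the top `d_out` leaves during systole, direct flow is
their overlap. The velocity-versus-phase waveform is trapezoidal with
zero samples at the ED/ES transitions, chosen so the linearly
phase-interpolated field integrates *exactly* to the configured
displacements; with substeps nested in frame intervals, RK4 is exact on
this field and the measured fractions match the slab-overlap truth to
well within 2%.

**Cohort simulator** (`simulate_cohort()`): two groups (defaults 19
controls, 12 AMI) with group-specific covariate distributions — controls
40 ± 16 y, 60 ± 10 bpm, 10/19 male; patients 66 ± 12 y, 79 ± 15 bpm,
11/12 male — and outcomes built as baseline + covariate effects +
planted group effect + Gaussian residual (default SD 1 outcome unit).
Default baselines and planted effects are typical control-level values
and adjusted group differences for the 11 parameters. Covariate effects
are centred at the control covariate means, so the group covariate gaps
confound the *unadjusted* comparison by construction — exactly the
structure the adjusted model must undo. The covariate coefficients
(−0.02 per year and −0.05 per bpm on L/min-scaled parameters, −0.05 and
−0.1 on percentage-scaled ones, +0.5/+1 for male sex) are package
choices fixed once to make that confounding material (about −1.3 L/min
on a mid-ventricular peak) without dominating the residual noise.

What the phantoms deliberately do not emulate: MR physics (k-space
sampling, VENC aliasing, eddy currents beyond the planted polynomial),
valve geometry, trabeculation, vortex formation, turbulence, and
registration error between velocity and cine grids (inputs are assumed
co-registered). Passing the phantom suite therefore demonstrates that
the estimators are correct on data satisfying their assumptions — not
that the pipeline is robust to acquisition artefacts in patient data.

## Numerical choices and conventions

* **Coordinates.** Voxel indices are 0-based; continuous positions in mm
  at voxel centers; world = index × spacing. Stored velocity components
  are in grid-axis direction; the apex-to-base sign is applied
  analytically via the mask's `apex_to_base_sign`, never by rewriting
  files.
* **RK4.** Fixed step = frame interval / `substeps` (default 10), no
  adaptivity, for bit-reproducibility. On a rigid-rotation field the
  endpoint error after one period at a 0.01 s step is below 1e-4 cm and
  scales as h⁴. Trajectories leaving the grid are frozen at their last
  in-grid position; non-finite velocities invalidate (and exclude) a
  trajectory.
* **Inside/outside tests** during classification use the mask of the
  temporally nearest frame (masks are discrete in time). A crossing is
  located at the first sample on the outside of the wall; transit beyond
  the basal end-plane, or through the lateral boundary of a base-region
  slice, counts as valid basal (valve-plane) transit.
* **Ties.** Peak flows and ED/ES take the earliest frame on ties.
* **Region weighting.** Regional flow averages slices with equal weight
  (not area-weighted); slices with an empty mask at a frame are skipped
  at that frame and logged.
* **ED/ES definition.** Frames of maximum/minimum cavity volume, with
  explicit overrides (`ed_frame`, `es_frame`) for volume-static data
  such as the plug phantom.
* **No multiple-testing correction** across the 11 group models; each is
  reported at its own alpha, stated here deliberately.
* **Pathline seeding density** is configurable (`density`, default 1 =
  every ED voxel; 0.25 = every other voxel along both in-plane axes,
  with seed volumes scaled so fractions stay volume fractions); the
  original seeding scheme for this analysis family is not standardised.

## Validation scales

The test suite exercises the study-scale phantom (1.25 mm, 20 frames)
for the flow, volume and EF oracles, and a 2.5 mm / 10-frame phantom —
the resolution of a typical low-noise pathline reconstruction — for
phase correction and the end-to-end runs. The cohort-level checks use
1000 null replicates for the type-I error of the adjusted model
(nominal 5%, accepted between 3.5% and 6.5%), 200 replicates for CI
coverage of a planted −3.9 L/min mid-ventricular effect under
confounding (accepted ≥ 90%), and a 31-subject synthetic image cohort
(19 + 12, 2.5 mm grid, quarter-density seeding) run twice to confirm
bit-identical result tables under fixed seeds. Per-parameter CI coverage
is the tested property; joint coverage across all 11 parameters at 95%
per-parameter intervals is necessarily lower (≈ 0.95¹¹ with independent
residuals) and is not a meaningful target.

## Known limitations

* Binary masks make sub-voxel wall positions invisible; near-apex slices
  carry large relative area error (see above).
* The nearest-frame inside/outside convention can misplace a crossing by
  up to half a frame interval; with 20 frames per cycle this is 2.5% of
  the cycle.
* Excluded-pathline percentages depend strongly on mask quality and
  temporal resolution; published patient values (median ≈ 24%) are a
  plausibility reference only, never a pass/fail bound.
* The cohort simulator draws outcome residuals independently across
  parameters; correlations between flow parameters within a subject are
  not emulated.
* Strain, LGE reading, registration and reconstruction are out of scope;
  segment scores and strain enter only as optional covariates.
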