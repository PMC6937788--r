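# lvflow

Regional left-ventricular hemodynamics from 4D-flow cardiac MRI, in R.

Acute myocardial infarction changes how blood moves through the left
ventricle: flow slows regionally (especially toward the apex), and the
end-diastolic blood pool shifts away from blood that transits the
ventricle in a single heartbeat toward blood that lingers for two or
more cycles — a pattern linked to apical stasis and thrombus risk.
`lvflow` implements the analysis pipeline that quantifies these changes
from two co-registered inputs per subject: a time-resolved
three-directional velocity field *v(x, t)* and a time-resolved binary
LV-cavity mask on the same short-axis grid. It is written for imaging
scientists who have segmented 4D-flow data in hand (or want to validate
such a pipeline end to end on synthetic phantoms with known truth).

## What it computes

For each subject, eleven LV flow parameters plus global function:

* **Through-plane flow** per short-axis slice and frame,
  `Q = mean(v_throughplane) × A`, with the LV long axis split into three
  equal-length regions (base, mid-ventricle, apex); peak systolic
  (positive, apex→base) and peak diastolic (magnitude of the most
  negative) flow per region, in L/min.
* **Kinetic energy indexed to EDV**:
  `KE_avg = (1/N_t) Σ_t Σ_vox ½ ρ V_vox |v_vox|²` with
  ρ = 1.06 g/cm³, in µJ, divided by end-diastolic volume (µJ/mL).
* **Flow compartments** by 4th-order Runge–Kutta pathline tracking from
  end diastole forward to end systole and backward to the previous end
  systole: direct flow, retained inflow, delayed ejection flow and
  residual volume as percentages of the end-diastolic blood pool;
  pathlines crossing the wall in the mid-ventricle or apex are excluded.
* **Ventricular function** from the cine mask (EDV, ESV, SV, EF, cardiac
  output) and infarct size from AHA 17-segment transmurality scores
  (mean score / 4).
* **Cohort statistics**: covariate-adjusted group differences from OLS
  models `parameter ~ group + age + sex + heart rate` (Δ with 95% CI and
  p per parameter), Welch t / chi-squared demographics, median ± IQR
  descriptives, and Spearman correlations of regional flow against
  standard CMR measures.

Background phase error is corrected beforehand by fitting a 3rd-order
3-D polynomial to static-tissue velocity and subtracting it everywhere.

Because no public dataset accompanies this kind of study, the package
ships first-class synthetic generators: a deforming half-ellipsoid LV
phantom with closed-form slice flux and volume curves, a plug-flow
cylinder with analytic compartment fractions, and a two-group cohort
simulator with planted, confounded group effects. Every pipeline stage
is tested against these oracles; see the methods vignette
(`vignettes/lv-4dflow-methods.Rmd`) for the models, conventions and
their limits.

## Worked example

Analyze one synthetic subject at the study's acquisition scale
(1.25 mm isotropic, 20 cardiac frames), then compare a simulated cohort:

```r
library(lvflow)

ph <- ellipsoid_phantom(R0 = 2, L = 8, alpha = 0.2, n_frames = 20,
                        spacing = 1.25)
rec <- analyze_subject(ph$field, ph$seg, heart_rate = 60, id = "phantom",
                       correct_phase = FALSE, density = 0.25, substeps = 6)
```

The record holds the 11 flow parameters and function metrics:

```
peak_systolic_base   3.40      # L/min, basal ejection peak
peak_systolic_mid    1.41
peak_systolic_apex   0.22      # apical flux is small by geometry
peak_diastolic_base  3.40      # filling mirrors ejection in this phantom
kei_edv              0.46      # uJ/mL; gentle wall motion, low KE
direct_pct          36.68      # % of EDV transiting in one beat
residual_pct        63.32      # % resident >= 2 cycles
excluded_pct         3.16      # pathlines lost through the wall (QC)
edv_ml              67.08      # voxel-counted; analytic (2/3)*pi*R0^2*L = 67.02
ef_pct              35.94      # analytic 1 - (1 - alpha)^2 = 36%
```

The phantom's EDV and EF land on their closed-form values, and the
compartment split matches what a reversible base-in/base-out flow
pattern must give: the stroke-volume fraction washes out directly, the
rest stays resident.

Cohort level — 19 controls vs 12 patients with planted adjusted effects
and confounded covariates:

```r
co <- simulate_cohort(seed = 1)
group_effects(co)
#> # A tibble: 11 x 6
#>   parameter          delta_mi conf_low conf_high     p_value     n
#> 1 peak_systolic_base   -2.73     -3.91     -1.54 0.0000685      31
#> 2 peak_systolic_mid    -4.11     -5.42     -2.80 0.000000790    31
#> 3 peak_systolic_apex   -0.165    -1.67      1.34 0.823          31
#> # ... 8 more rows
```

The planted mid-ventricular effect of −3.9 L/min is recovered by the
adjusted model (−4.11, CI [−5.42, −2.80]) despite the groups differing
in age, sex and heart rate by construction.

`autoplot()` methods exist for flow curves, compartment analyses and
volume curves; `tidy()`/`glance()` for fitted group models. A thin
command-line wrapper for simulation and cohort analysis is in
`inst/scripts/lvflow.R`.

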