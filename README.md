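# ea4dflow

Transmitral E/A ratio quantification from 4D Flow cardiovascular MRI.

## The problem

The ratio of the peak early (E) and late (A) diastolic transmitral inflow
velocities is the first-line index for grading left-ventricular diastolic
dysfunction. It is conventionally measured with Doppler echocardiography;
4D Flow CMR — time-resolved phase-contrast MRI with three-directional
velocity encoding — acquires the full intracardiac velocity field
**v**(x, t) in one examination and allows the same physiology to be
quantified retrospectively, at any location, and automatically.

`ea4dflow` is for researchers building or evaluating such pipelines. It
implements three measurement methods:

* **MVvel** — peak of the maximum through-plane velocity on a tracked
  mitral annulus plane, corrected for the plane's own motion:
  `v⊥(u, t) = v(x(u), t) · n(t) − v_plane(t)`, maximised over the
  segmented inflow area per frame.
* **MVflow** — volumetric inflow rate through the same plane,
  `Q(t) = Σ v⊥ ΔA` (mL/s).
* **LVvel** — maximum speed `|v|` at any site inside an LV mask per frame
  (the automated method; the mask is an input).

For each curve, the two most prominent diastolic maxima give
`E/A = v_E / v_A`; monophasic (fused) inflow, where E and A cannot be
discerned, is detected and flagged rather than mis-measured. Around the
methods sit velocity preprocessing (temporal phase-unwrapping for
aliasing, polynomial background-phase correction), normalized
cross-correlation valve tracking from a long-axis cine, a synthetic 4D
inflow phantom with analytic ground truth, and the method-comparison
statistics used in clinical validation work (OLS regression, Bland-Altman
with mean ± 2 SD limits of agreement, paired t tests, Fisher r-to-z
comparison of correlations, R² association categories).

## Worked example

Generate the default phantom (vena-contracta peaks E 60, A 50 cm/s, so the
true E/A is 1.2), track the annulus on its cine, and run all three methods:

```r
library(ea4dflow)
library(dplyr)

params <- phantom_params()          # 2.8 mm voxels, 30 frames, VENC 120 cm/s
phantom <- generate_phantom(params)

tracks <- track_landmarks(phantom$cine, phantom$landmarks$points_mm,
                          init_frame = phantom$landmarks$frame_index)
plane <- plane_velocity(landmarks_to_plane(tracks, phantom$cine,
                                           apex_hint = c(56, 56, 140)))

map    <- mv_velocity_map(phantom$field, plane)
mvvel  <- detect_ea_peaks(max_velocity_curve(map))
mvflow <- detect_ea_peaks(flow_rate_curve(map))
lvvel  <- lvvel_ea(phantom$field, phantom$lv_mask)

bind_rows(tidy(lvvel), tidy(mvvel), tidy(mvflow))
#> # A tibble: 3 × 9
#>   kind      e_value a_value e_time a_time ea_ratio fused window_start window_end
#>   <chr>       <dbl>   <dbl>  <dbl>  <dbl>    <dbl> <lgl>        <dbl>      <dbl>
#> 1 lv_max_s…    57.9    48.3   533.    900     1.20 FALSE         433.       967.
#> 2 max_velo…    52.8    45.0   533.    900     1.17 FALSE         433.       967.
#> 3 flow_rate   620.    545.    533.    900     1.14 FALSE         433.       967.
```

Reading the table: all three methods land the E peak at 533 ms and the A
peak at 900 ms — the true pulse centres. LVvel recovers the vena-contracta
peaks to within a few percent (57.9/48.3 vs 60/50 cm/s; the 3×3×3 median
filter trades a little amplitude for noise robustness) and the ratio to
0.1%. MVvel reads systematically lower (52.8/45.0) because the annulus
plane sits 5 mm upstream of the vena contracta — yet its E/A of 1.17 stays
within 3% of truth, the underestimation cancelling in the ratio. MVflow
reports flow rates (620 and 545 mL/s) whose ratio, 1.14, tracks the
analytic volumetric ratio. `autoplot(curve, peaks)` draws any curve with
its detected peaks; `run_comparison()` turns per-subject tables of such
measurements into the full regression/Bland-Altman agreement panel.

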