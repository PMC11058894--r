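---
title: "Measuring the transmitral E/A ratio from 4D Flow CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the transmitral E/A ratio from 4D Flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ea4dflow)
```

## Background

Transmitral inflow during diastole is biphasic: an early filling wave (E),
driven by ventricular relaxation, and a late wave (A) from atrial
contraction. The ratio of their peak velocities, E/A, is the first-line
index for grading left-ventricular diastolic dysfunction, conventionally
measured with pulsed-wave Doppler echocardiography at the mitral leaflet
tips. Time-resolved, three-directionally velocity-encoded phase-contrast MRI
("4D Flow CMR") measures a full velocity vector field over the heart once
per examination, so the same E/A physiology can be quantified
retrospectively, at any location, without the beam-alignment constraint of
Doppler.

This package implements three measurement strategies on such velocity
fields:

* **MVvel** — the maximum through-plane inflow velocity on a mitral annulus
  plane that is tracked over the cardiac cycle, corrected for the plane's
  own motion.
* **MVflow** — the volumetric inflow rate (mL/s) through the same tracked
  plane, integrating through-plane velocity over a segmented inflow area.
* **LVvel** — the maximum speed at *any* site inside a left-ventricular
  (LV) mask per timeframe, without constraint to the mitral plane. Because
  the peak inflow velocity occurs at the vena contracta, a few millimetres
  downstream (apical) of the annulus, the annular methods systematically
  underestimate absolute peak velocities relative to LVvel while all three
  agree closely on the *ratio* — the underestimation is common to E and A
  and largely cancels.

A fourth component, the agreement-statistics layer, reproduces the usual
method-comparison machinery (ordinary least-squares regression, Bland-Altman
limits of agreement, paired t tests, Fisher r-to-z comparison of
correlations, R²-based association categories).

## Processing model

### Preprocessing

Velocities beyond the encoding limit VENC alias into `[-VENC, VENC)`.
`unwrap_velocity()` unwraps each voxel's time course *temporally*: frame 0
is assumed alias-free (anchor the reconstruction at end-diastole, where
velocities are low) and each subsequent sample is moved by the multiple of
`2*VENC` closest to its predecessor. This is the simplest contract that is
exact for single wraps on cyclic cardiac data; its documented failure mode
is aliasing in frame 0 itself. Background phase offsets are modelled by
`correct_background_phase()` as a spatial polynomial (order 0–2, default 1)
per velocity component, fitted by least squares to the *time-averaged*
velocity over static tissue and subtracted from every frame. Fitting the
temporal mean rather than each frame reflects the quasi-static nature of
eddy-current offsets; static voxels are supplied as a mask or auto-detected
(temporal-mean speed and temporal SD both under 2 cm/s by default).
Concomitant-gradient corrections are assumed already applied on the scanner
and are out of scope.

### Valve tracking

The mitral annulus is tracked on a long-axis cine from a single
end-diastolic initialisation of two annulus landmarks (a JSON seed file
replaces interactive clicking). The tracking primitive is normalized
cross-correlation template matching (21×21 px template, ±10 px search,
both configurable), run once forward and once backward around the cyclic
cardiac cycle, with quadratic subpixel refinement of the correlation peak.
The two passes are fused with weights that decrease linearly with the
number of steps from the start frame — at a frame reached after `t` of `T`
forward steps the fused position is `(T−t)/T` forward + `t/T` backward —
so the track is exact at the initialisation and the least-certain ends of
each pass contribute least. One subtlety is worth recording: the NCC
displacement measures the feature's motion relative to its (sub-pixel)
position inside the template, so it must be accumulated onto the
*continuous* previous position; accumulating onto the rounded patch centre
re-injects a rounding error per frame that random-walks into pixel-scale
drift. Tracking failure is declared when the NCC peak falls below 0.3 on
more than 25% of frames.

The tracked chord defines the plane per frame: origin at the chord
midpoint, the plane containing the chord and the cine through-plane
direction, the normal perpendicular to the chord within the image plane and
oriented toward the apex (so diastolic inflow is positive). The plane's own
normal velocity — needed to express inflow relative to the moving annulus —
comes from central differences with cyclic boundary.

### Mitral-plane quantification

Velocities are reformatted onto a 50 mm × 50 mm grid (1 mm spacing) on the
tracked plane by trilinear interpolation of the three components and
projection onto the plane normal; samples outside the acquired volume are
zeroed and excluded. The map is corrected for plane motion (subtracting the
plane's normal velocity), median-filtered with a 3×3 kernel (replicated
edges), and the inflow area is segmented: threshold at
`max(5 cm/s, 15% of the frame maximum)`, keep the connected component
containing (or nearest to) the grid centre, fill holes. The segmentation
rule is entirely this package's design — thresholds are exposed as
arguments. MVvel takes the per-frame maximum of the filtered map inside the
mask (the mask-restricted maximum is a deliberate choice; the alternative
whole-plane maximum would be sensitive to neighbouring structures); MVflow
sums velocity over the mask times pixel area.

### LV quantification

LVvel computes voxel speed (the Euclidean norm of the three components),
median-filters it with a 3×3×3 kernel, and takes the per-frame maximum
inside the supplied LV mask. Filtering the full volume *before* masking
avoids mask-boundary artifacts from edge replication; the order is exposed
as a switch. The median filter deliberately trades a few percent of peak
amplitude for robustness against isolated noisy voxels — the same trade
made in clinical processing — and is the main reason measured peaks sit
slightly below the analytic truth on noise-free phantoms. The LV
segmentation itself is an input (for phantoms, the ground-truth mask): the
upstream deep-learning segmentation of real examinations is out of scope.

### Peak detection

All three methods share `detect_ea_peaks()`. The curve is restricted to a
diastolic window — user-supplied, or automatically from the first positive
sample at or after cycle fraction 0.35 to the last frame (the fraction is
configurable; ventricular systole occupies roughly the first third of the
cycle). Local maxima are samples strictly greater than both neighbours,
plateaus collapsing to their first sample; maxima with prominence below 10%
of the window maximum are discarded; the two largest survivors become E
(earlier) and A (later). Ties resolve by value, then prominence, then
earlier time, making the selection bit-reproducible. If fewer than two
peaks survive, the curve is flagged `fused` — the monophasic-inflow
situation (typically E/A merging at high heart rate) in which an E/A ratio
cannot be reported and which excludes a dataset from comparison; flat or
empty windows warn rather than error.

### Agreement statistics

`run_comparison()` assembles, per method pair and metric, the regression
`y = β₁x + β₀` with R² (squared Pearson correlation), Bland-Altman mean
difference with limits of agreement at mean ± 2 SD (exactly 2, not 1.96),
the mean percentage difference computed per pair as
`100·(d₁−d₂)/((d₁+d₂)/2)`, the paired t test, and an association category
(weak R² ≤ 0.25 < moderate ≤ 0.5 < strong ≤ 0.8 < very strong ≤ 1).
`fisher_rz_compare()` compares two correlations through `atanh`; the
default is the independent-samples statistic
`z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))` with a one-sided
upper-tail p. When the two correlations share a variable on the same
subjects the dependent-sample (Steiger) variant is available via
`method = "dependent"`; the independent form remains the default because it
is what the plain name "Fisher's r to z" denotes.

## The synthetic phantom

Because no patient data ship with the package, every end-to-end claim is
validated on `generate_phantom()`, which emulates the statistical structure
the methods assume, with analytic ground truth:

* **Acquisition**: 2.8 mm isotropic voxels, 30 frames over a 1000 ms cycle
  (≈33 ms frame spacing, comparable to a ~53 ms acquired temporal
  resolution after reconstruction), VENC 120 cm/s — typical whole-heart 4D
  Flow settings.
* **Inflow**: a transmitral jet along the LV long axis whose through-plane
  velocity is separable — temporal envelope = sum of two raised-cosine
  pulses (defaults: peak E 60 cm/s at cycle fraction 16/30, half-width
  130 ms; peak A 50 cm/s at 27/30, half-width 100 ms; E/A = 1.2, a normal
  adult pattern), Gaussian lateral cross-section of scale `jet_radius`
  (15 mm, truncated at 3σ, giving a ~28 cm² effective area and peak-E flow
  in the physiologic several-hundred mL/s range), and an asymmetric axial
  profile peaking 5 mm apical to the annulus (the vena contracta), decaying
  with a 10 mm scale toward the atrium and 20 mm toward the apex. The
  default peak times are frame-commensurate so the sampled curves attain
  the analytic peaks: the phantom is a measurement target, not a model of
  timing jitter.
* **Annulus motion**: sinusoidal longitudinal excursion (8 mm peak-to-peak
  by default, in the range seen in ischemic cohorts), with the two annulus
  landmarks rendered as Gaussian blobs over a faint static texture in a
  long-axis cine, so NCC tracking is well-posed.
* **Systolic outflow**: an oppositely-directed jet inside the LV mask
  (80 cm/s peak at cycle fraction 0.18) ensures that an *unwindowed*
  maximum-speed analysis would wrongly report systole — the diastolic
  window is therefore load-bearing and tested.
* **Degradations**: optional per-component Gaussian noise and optional
  aliasing injection (modular wrapping into `[-VENC, VENC)`).
* **Truth**: analytic peak velocities, flow rates (envelope × effective
  truncated-Gaussian area at the annulus offset), the landmark trajectory,
  the LV mask, and a fusion flag computed from the summed envelope.

What the phantom does **not** emulate: MR physics (k-space sampling,
partial-volume and intravoxel dephasing, SENSE noise structure), beat-to-beat
averaging, valve leaflets, lateral jet migration between E and A, or
realistic myocardial texture. Passing the recovery tests therefore shows
the *processing chain* is correct and self-consistent at clinical
resolution — not that clinical accuracy on patients is guaranteed.

## Validation conditions and numerical choices

The validation suite uses the default 41×41×55-voxel, 30-frame phantom for
end-to-end recovery (noise-free: LVvel E/A and peaks within 5%, MVvel E/A
within 5%, MVflow E/A within 10% of the analytic flow ratio), three further
phantom configurations for the underestimation ordering, 20 seeded
replicates at 5 cm/s noise for robustness (E/A within 10% in at least
18/20), and 1000 random instances per statistical routine against
independent brute-force oracles (normal equations, two-pass moments, O(n²)
peak scans) at 10⁻¹⁰. A 25×25×35-voxel phantom with a proportionally
smaller jet serves the structural tests.

Numerical conventions worth knowing: trilinear interpolation for all
resampling (out-of-volume samples excluded rather than extrapolated);
median filters use replicated edges; the curve "period" for the cyclic
boundary and the automatic window is `n · mean(diff(frame_times))`;
Bland-Altman percentage differences divide by the per-pair mean (division
by a zero pair-mean errors with the offending index named); sample SDs use
the n−1 denominator; all randomness flows through explicit integer seeds.

## Limitations

* Temporal unwrapping cannot recover a field aliased at the anchor frame.
* The two-landmark chord assumes the annulus stays well represented by the
  long-axis cine plane; through-plane annular motion is not modelled.
* The inflow segmentation thresholds are heuristic; on strongly eccentric
  or regurgitant flows they should be reviewed per dataset.
* Absolute peak velocities are, by design of the median filters and the
  annular measurement site, lower bounds on the vena-contracta velocity;
  only the E/A ratio is bias-cancelling.
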