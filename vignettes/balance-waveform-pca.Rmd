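---
title: "Methods: time-to-boundary posturography and waveform PCA for single-leg balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-to-boundary posturography and waveform PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

posturekit analyses single-leg balance trials performed on a static or a
mediolaterally oscillating platform, for two-group designs (typically
chronic ankle instability, CAI, versus healthy controls, HC). This
vignette documents the models the package implements, the parameters
that matter, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## The paradigm and its signal chain

A trial is at least 15 s of single-leg stance recorded as 3D marker
trajectories (100 Hz) and force-plate forces/moments (1 kHz). The moving
condition adds a sinusoidal mediolateral platform displacement, by
default 1.6 Hz at 20 mm peak-to-peak — `platform_spec()`. At that
frequency/amplitude the peak platform acceleration is
$A(2\pi f)^2 \approx 1.01\ \mathrm{m/s^2}$; the generator follows the
stated frequency and amplitude and does not clamp acceleration to a
round 1 m/s².

Conditioning follows standard gait-lab practice:

* **Filtering** (`butterworth_lowpass()`): 4th-order 10 Hz low-pass
  Butterworth, applied forward and backward so the output is zero-phase
  and kinematic and kinetic channels stay time-aligned. No cutoff
  correction is applied for the dual pass. Edge transients are
  suppressed by odd-reflection padding (3 time constants,
  `3 * rate / cutoff` samples) with steady-state filter initialisation;
  the residual edge error decays within ~0.1 s and falls entirely inside
  the 2.5 s that trimming discards. Near the band edge the bilinear
  transform warps the digital response slightly differently at 100 Hz
  and 1000 Hz, so filtering and resampling commute to high precision for
  signals well inside the passband (tested at 1.6–2 Hz) but only
  approximately at 4–8 Hz.
* **Resampling** (`spline_downsample()`): force data are brought to the
  common 100 Hz grid by cubic-spline interpolation (exact on cubics).
* **Trimming** (`trim_to_middle_10s()`): the analysed window is exactly
  `round(10 s × rate)` samples — 1,000 time points at 100 Hz. Moving
  trials anchor the window start at the platform zero crossing moving
  *medially* (toward the stance-side body midline: −X for a right
  stance) nearest the trial centre, ties resolved toward the earlier
  crossing; crossing times are linearly interpolated and rounded to the
  nearest sample. Static trials have no event to anchor on, so the
  centred window is used. Indexing is 0-based and half-open.

## Joint kinematics

Segment frames for foot, shank, thigh, pelvis and torso are estimated
per sample by a least-squares rigid-body (orthogonal Procrustes) fit of
each marker cluster to its template geometry, via SVD with a determinant
correction, so every returned rotation is exactly proper-orthogonal
(orthonormality within 1e-9 is asserted in tests). A Procrustes fit was
chosen over direct anatomical-axis construction because it degrades
gracefully under marker noise; with 0.5 mm isotropic noise the frame
orientation error stays below 0.5° RMS for the default clusters.

Joint angles decompose the relative rotation of adjacent segments,

$$R_\mathrm{rel} = R_\mathrm{prox}^\top R_\mathrm{dist}
  = R_x(\alpha)\,R_y(\beta)\,R_z(\gamma),$$

with X the mediolateral (flexion) axis → sagittal angle, Y the
anteroposterior axis → frontal angle, Z the longitudinal axis →
horizontal angle. The chain is ankle (foot–shank), knee (shank–thigh),
hip (thigh–pelvis) and torso (pelvis–torso). Angles are unwrapped per
channel (180° jump tolerance) before differentiation, and samples with
$|\beta| > 85°$ are flagged as gimbal-proximate (never reached by the
generator's angle ranges).

**Left-stance handling.** Left trials are mirrored about the body
midline (lab X negated) and processed in the right-stance frame. No
per-channel sign flips are needed: rotations about the mediolateral axis
are reflection-invariant, and frontal/horizontal motions mirror onto
their anatomical counterparts (inversion reads as inversion, internal
rotation as internal rotation). This makes "reflect a right-stance
trial" and "generate the equivalent left-stance trial" literally
identical operations, which is asserted in tests.

**Angular velocity.** Velocity is the first time derivative of the
joint angle (central differences, one-sided at the window ends, exact on
linear series). A literal second derivative is an acceleration, not a
velocity; because source descriptions of this paradigm sometimes say
"second derivative", `angular_velocity(mode = "second")` reproduces that
reading explicitly, but `"first"` is the default and is what the
pipeline uses. Discrete measures are range of motion (max − min, °) and
RMS angular velocity (°/s) per channel over the trimmed window.

## Centre of pressure and time-to-boundary

COP comes from the standard plate formula (with plate-surface offset
`d_z` and origin offset, both 0 by default); samples must carry at least
20 N of vertical load (configurable). The foot is modelled as a
rectangle: the long axis is the trial-averaged, horizontal-plane unit
vector from the calcaneus to the first-distal-phalanx marker, and the
rectangle is the bounding box of the four trial-averaged border-marker
projections in the (long-axis, mediolateral) foot frame. For
moving-platform trials both the COP (plate-referenced, and the plate
rides the platform) and the boundary (anatomical, from markers with the
platform displacement removed) live in the support-surface frame, so
TTB measures COP-relative-to-foot motion.

TTB-ML divides the signed distance to the rectangle edge the COP is
moving toward by the mediolateral COP speed (central differences of the
filtered, 100 Hz COP). Conventions, all configurable:

* near-zero velocity (|v| < 1e-6 m/s): the sample takes the cap value
  (the 10-s window length) and is flagged invalid — capped samples never
  produce minima;
* COP outside the rectangle: TTB clipped to 0 and flagged; a trial with
  more than 5% outside samples raises a boundary-mismatch warning;
* local minima are valid samples strictly lower than both neighbouring
  distinct values, plateaus counted once at their first sample, and are
  only sought inside maximal runs of valid samples; a trial with no
  interior minimum is flagged degenerate rather than silently
  summarised.

Summaries are the mean and sample SD over the local minima and the
global minimum over valid samples (`absolute_minimum ≤ mean_of_minima`
always). Sway metrics: SDAmp is the sample SD of the COP distance from
its mean position; sway velocity is path length over the traversed
duration `(n − 1)/rate`. A useful exact mechanic (and the lever the
generator uses to plant group effects): traversing the same COP path k
times faster divides every valid TTB sample, and hence all three
summaries, by k.

## The waveform PCA procedure

Per condition: (1) average each participant's three trimmed trials
pointwise; (2) lay the averages out as one row per participant with
12,000 variables — channel-major, i.e. variable `(c−1)·1000 + t` is time
point `t` of canonical channel `c`; (3) z-score each variable *across
participants*, $Z_t = (X_t - \mu_t)/s_t$ with the sample SD, dropping
(and reporting) variables with SD below 1e-12. Computing $\mu_t, s_t$
across participants is the only coherent reading: a per-participant SD
of a single scalar does not exist. (4) SVD of the standardized matrix;
components are retained until cumulative explained variance reaches 90%.
Component signs are a pure convention and are fixed so the reference
group's (HC) mean score is non-negative; tests assert that flipping a
loading together with its scores changes neither reconstructions nor p
values. (5) Independent t-tests on each retained component's scores —
pooled-variance by default (Welch via `var_equal = FALSE`), Cohen's d
with n−1-weighted pooled SD, and *no* multiple-testing correction, but
the family size is attached to the result so readers can judge it.
(6) Interpretation by reconstruction,
$\hat X = \mu + s \odot (\bar{PCS} \cdot PCV)$, mapping group-mean
scores of selected components back to degrees.

**Leave-one-out surrogate validation.** The standardization and PCA are
refit n times on the remaining n−1 participants (45 × 12,000 at study
scale). Component order and sign are not stable across refits, so each
surrogate is matched to the full-fit target component by maximal
absolute loading correlation with sign alignment; matches whose top two
candidates lie within 0.01 of each other are flagged ambiguous and both
are reported. The group test is re-run on the matched scores and each
surrogate classified significant (p < .05), marginal (.05 ≤ p < .10) or
non-significant.

## Inferential layer

The three TTB summaries feed a mixed 2×2 ANOVA (between: group; within:
condition) built on `stats::aov` with an `Error(participant)` stratum;
partial eta squared uses each effect's own stratum error,
$\eta_p^2 = SS_\mathrm{eff}/(SS_\mathrm{eff}+SS_\mathrm{err})$, and is
verified in tests against a from-scratch sums-of-squares decomposition
to 1e-9. Post hocs are Bonferroni-adjusted (m = 2 per family: groups
within each condition, independent t; conditions within each group,
paired t) with 95% CIs of the differences. Which family Bonferroni
should span is genuinely underdetermined in this paradigm; m = 2 per
framing is the package's documented choice. Shapiro–Wilk diagnostics are
provided (`normality_check()`) but never gate computation.

Stepwise regression of the TTB mean of minima on the 12 RMS
angular-velocity channels is forward selection by smallest partial-F p
value with entry/removal thresholds 0.05/0.10 (both configurable and
recorded in the result). Two cautions are inherent to the method and
documented rather than patched: with 11 null candidates a spurious
predictor also clears p < .05 in roughly 40% of data sets, and removal
steps can lower R² (the ladder is non-decreasing over additions only).
The final model is a plain `lm` refit, so reported coefficients, CIs and
the overall F are exactly reproducible from the selected set.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the study's *design*: 23 participants per
group by default, 3 trials per participant-condition, 15-s trials, both
platform conditions, the marker/force sampling rates, and planted group
structure:

* **Joint-angle offsets** (`group_effect_spec()$offsets`, degrees,
  CAI − HC): signed per the reported CAI stance pattern (more
  dorsiflexed/inverted/internally-rotated ankle, more flexed knee, less
  flexed hip and torso, more adducted and externally rotated hip, …)
  with magnitudes of 0.5–1.5° — free parameters of the generator, as
  only directions, not synthetic magnitudes, are constrained by the
  literature. Between-participant baseline SD is 2° per channel and
  trial-to-trial jitter 0.5°, giving a planted multichannel separation
  of d ≈ 1.8 — detectable by the PCA route in well over 90% of cohorts
  (asserted over 100 seeded runs).
* **Entrainment**: in the moving condition each channel adds a sinusoid
  at the platform frequency (largest frontal-plane amplitudes at the
  ankle, 3°), with participant-specific phase (SD 0.3 rad) and amplitude
  (log-normal, SD 0.15). Static trials contain no component at the
  platform frequency above the noise floor (tested spectrally).
* **Angle noise**: white Gaussian coloured by an AR(1) with coefficient
  0.95 at 100 Hz, normalised to a 1° stationary SD — physiological sway
  is low-frequency dominated and no noise spectrum is prescribed by the
  paradigm, so this is a deliberate, simple choice.
* **Sway/TTB structure**: the COP is a mean-reverting (discretised
  Ornstein–Uhlenbeck) process inside the foot rectangle (stationary SD
  7 mm ML, reversion 1.2 /s), time-rescaled per group × condition by
  `vel_scale`. Because the 10 Hz filter band-limits the sway velocity,
  realised TTB falls roughly with the square root of the scale; the
  default matrix (CAI 3.2 / HC 1.2 static; 27 / 22 moving) was
  calibrated once through the full force-to-TTB chain so that generated
  cell means show the intended pattern — a CAI deficit on the static
  platform, near-equal groups on the moving platform, and a strong
  condition effect — and then frozen. Forces and moments are
  constructed to invert the COP formula exactly (the constructed-inverse
  tests demand recovery to 1e-9 m).
* **Markers**: forward kinematics of a five-segment template
  (overridable order-of-magnitude anthropometry: foot 0.25 × 0.10 m,
  shank/thigh 0.40 m, pelvis 0.25 m, torso 0.50 m) with 0.5 mm default
  marker noise; cluster geometries are spread widely enough that this
  noise keeps frame errors below 0.5° RMS.

Passing tests on these cohorts show the *pipeline* is correct —
round-trips recover planted angles and COP exactly, planted effects are
recovered at their designed size, and null cohorts reject at the nominal
α (calibration asserted at 1000 replicates within ±2 percentage
points). They do not show that real CAI cohorts behave like the
generator: real data have soft-tissue artefact (not rigid-cluster
noise), non-stationary sway, failed/repeated trials, marker dropout
beyond the simple gap model (gaps ≤ 10 frames are spline-filled; longer
gaps are a hard error), and — importantly — whatever true coupling
exists between joint angular velocity and TTB. The generator plants its
kinematic and its stability effects through separate mechanisms, so the
stepwise regression behaves as a null on synthetic cohorts; study-scale
regression results (like a sizeable R² with ankle/hip velocity
predictors) are properties of human data that this package can test for
but not manufacture.

## Problem sizes and runtime choices

The test suite exercises full 46-participant dimensionality where the
structure demands it (the 46 × 12,000 PCA and its 46 leave-one-out
surrogate fits) and uses smaller cohorts (2–6 per group), shorter
windows (1–2 s) or reduced force rates (200–500 Hz) for Monte-Carlo
properties, chosen so the planted structure, not the sample count,
drives each assertion: 100 seeded cohorts for planted-effect power, 1000
replicates for null calibration, 200 for the stepwise null rate. The
acceptance script runs the full study scale (46 participants, 276
trials, markers and 1 kHz forces throughout) in about a minute.

## Known limitations

* No C3D reader (TRC and wide CSV only), no musculoskeletal or
  forward-dynamics realism, no ground-reaction-force realism beyond
  COP consistency, no anteroposterior TTB, and no varimax or functional
  smoothing of the PCA basis.
* The Euler X-Y-Z decomposition is ill-conditioned near |β| = 90°;
  flagged, not corrected.
* Surrogate matching assumes the target component survives the refit as
  a recognisably correlated loading; wholly unstable components surface
  as low `loading_cor` and ambiguity flags rather than errors.
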