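---
title: "Models and methods of the proprioceptive-encoding pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the proprioceptive-encoding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proprio)
```

This vignette documents the models implemented by `proprio`, the parameter
choices behind them, what the synthetic-data generators emulate, and the
numerical decisions a user should know before trusting the outputs.

## The experimental paradigm being modelled

A head-fixed mouse holds the endpoint handle of a planar five-bar pantograph
driven by two motors. Passive displacements of the forelimb (5–8 mm at
2–3 cm/s with a trapezoidal velocity profile, in eight co-planar directions)
are delivered while either (a) two-photon calcium imaging records single
neurons in forelimb somatosensory cortex, (b) wide-field dual-channel imaging
maps activation across dorsal cortex, or (c) the animal reports the movement
direction in a two-alternative forced-choice lick task. The package contains
the analysis for all three arms plus the robot/limb kinematics that tie
stimulus geometry to joint angles.

## Kinematics

**Pantograph.** Motors sit at the origin and at (d, 0); each drives a
proximal link of length `lp` whose distal link (`ld`) meets the other chain
at the endpoint. Forward kinematics intersects the two distal-link circles
and takes the elbow-up (larger-Y) branch; inverse kinematics prefers the
outward working mode (left elbow clockwise of the motor-to-target ray, right
elbow counterclockwise) and verifies the choice by a forward round trip.
The link dimensions are configuration (defaults d = 2, lp = 2, ld = 3 cm):
the published design is cited without dimensions, so these are package
defaults, not claims about the hardware. Round-trip error is below 1e-9 cm
over the workspace (asserted in the tests).

**Trajectories.** Point-to-point displacements use a trapezoidal speed
profile with configurable acceleration (default 20 cm/s²; only the peak
velocity is stated for the hardware). When the distance is shorter than
v²/a the profile degenerates to a triangle. Sampling is 1 kHz; the speed
integral reproduces the commanded amplitude to 0.1%.

**3D joint tracking.** Stereo pixel pairs for the five landmarks
(scapulothoracic, glenohumeral, elbow, wrist, endpoint) are triangulated by
the homogeneous direct linear transform; no iterative refinement is applied
by default, keeping results deterministic. Camera-to-manipulandum
registration fits a similarity transform (rotation + isotropic scale +
translation, det(R) = +1 enforced through the SVD sign correction, so a
mirrored correspondence can never silently flip the anatomy). The humerus
abduction/adduction angle is the azimuth of the glenohumeral-to-elbow vector
projected on the XZ plane, measured from −Z, positive toward +X (lateral);
workspace angle maps interpolate bilinearly on the measurement lattice, and
movement-wise angle changes are differences of interpolated values.

## Two-photon trace analysis

**Motion shifts** are integer-pixel argmaxima of the FFT cross-power between
image and template after cropping 10% from each border; ties break toward
the smallest |dx|+|dy|. Sub-pixel refinement is deliberately not applied.

**Deconvolution.** Spike amplitudes are inferred under the AR(1) indicator
model c[t] = γ·c[t−1] + s[t], γ = exp(−dt/τ) with τ = 0.8 s, by exactly
minimizing ½‖c−y‖² + λ·Σs subject to s ≥ 0 with a pool-adjacent-violators
pass (the standard online algorithm for this convex problem). λ defaults to
a robust per-sample noise estimate, MAD(diff(y))/√2; λ = 0 gives exact
inversion of noiseless traces (asserted: reconvolution RMSE < 1e-6). The
tests also check the solution against a brute-force box-constrained
quadratic-programming oracle on a small trace.

**Rate densities** place spikes on a 1 kHz grid and convolve with a Gaussian
kernel normalized to unit sum on that grid, times the grid rate. The stated
kernel "width" of 0.1 s is interpreted as σ (not FWHM); this is configurable.
The time integral of the density equals the inferred spike count.

**Evoked responses** are max(post-window) − mean(pre-window) with windows
[0, 1.5] s and [−0.75, 0) s around onset. The trial-mean of per-trial values
is used when aggregating (whether the original procedure took per-trial
maxima before or after averaging is not stated; trial-mean is the default).

**Randomization test.** The observed mean evoked response over the onset set
is compared with 1999 null values, each obtained by one uniform circular
shift of the entire onset set across the session (this preserves event count
and spacing and is the standard exchangeable null; independent per-event
placement is available behind a flag). The threshold is the empirical
(inverse-CDF) 99th percentile of the 1999 null values, which makes
"observed > threshold" identical to the exact permutation rule
p = (1 + #{null ≥ obs})/2000 ≤ 0.01. On 2000 synthetic null neurons the
measured false-positive rate is consistent with the nominal 0.01 (checked in
the acceptance suite at 0.01 plus two binomial standard errors).

## Directional tuning

Per-direction mean peak responses are fitted with
f(x) = b₀·exp(−((x−b₁)/b₂)²) after circularly re-centering the direction
axis on the empirical maximum, so wrap-around is handled by re-centering
rather than a periodic model; b₁ is mapped back to absolute degrees.
Fitting uses `nls(algorithm = "port")` from three width starts (40°, 70°,
110°), keeping the lowest-RSS solution; confidence intervals are t-based
from the analytic-Jacobian covariance at the optimum. A neuron is
*directionally selective* when both the b₀ and b₂ 95% CIs exclude zero and
the fitted width stays within the half-circle (b₂ ≤ 180°): on a ±180°
re-centered axis a Gaussian wider than the domain is indistinguishable from
flat tuning, and without this cap flat noisy neurons occasionally converge
to b₂ ≈ 250–450° with deceptively tight intervals. With the cap, flat-tuned
noisy neurons are flagged in ≤ 5% of simulations while genuinely tuned
neurons (widths 30–120°) are detected in ≈ 99%.

Population statistics: preferred-direction distributions are tested with the
Rayleigh test (z = n·R̄² with the standard small-sample p approximation).
The forward/return analysis converts preferred movement directions to
preferred spatial-position angles — for home-to-target movements the
position angle equals the movement direction; for target-to-home movements
it is the movement direction + 180° (the position of the trial's non-home
endpoint, seen from the home position). A population tuned to the movement
vector therefore shows per-neuron shifts at 180°, a position-tuned
population at 0°; both limits are asserted exactly in the tests. The
peripersonal statistic Δratio = (x̄−ȳ)/max(x̄,ȳ) compares mean peak
responses between matched movement conditions; per-neuron significance is a
two-sided Welch t-test at α = 0.01 and population means are tested against
zero. Kinematic sensitivity regresses per-trial peaks on amplitude or
velocity and reports the percent change for a doubling, evaluated at the
midpoint of the tested range (the reference value is not stated in the
source procedure; the midpoint is symmetric and always interior).

## Wide-field processing

Interleaved blue/violet frames are demultiplexed and linearly interpolated
per pixel onto a shared regular 20 Hz grid. For each pixel the blue series is
regressed on the violet series *with an intercept* (the two channels have
different DC levels), the scaled violet series is subtracted, and the
residual is converted to Δf/f₀ using the mean of the 1 s pre-stimulus
baseline of the blue channel as f₀. Smoothing is Savitzky–Golay with a
450 ms window (9 samples at 20 Hz) and order 2, implemented as a banded
projection matrix whose edge rows use the polynomial edge filters, so exact
quadratics pass through unchanged everywhere. After smoothing, the per-pixel
baseline mean is subtracted again so the baseline of the returned Δf/f₀ is
exactly zero. Zero-variance violet pixels are masked and logged. The
regression is fitted over the whole (trial-averaged) series, matching a
pipeline that averages > 80 trials per session before correction.

The peak-activation frame maximizes the spatial mean (optionally within a
mask; earlier frame wins ties) and is normalized to its own maximum. Atlas
registration is a least-squares 2D affine from ≥ 3 matched landmarks (five
are expected: bregma, lambda, the anterolateral parietal-bone tips, and the
median frontal-pole point); the atlas is an abstract coordinate frame
supplied through the landmark file — no atlas raster ships with the package.
Activation outlines are the 0.5 iso-contours of the normalized map, keeping
the connected component containing the peak.

## Behavior

The side-bias controller keeps the last 10 non-aborted trials; the bias is
the medial minus lateral fraction of correct answers, with an empty side
contributing 0 (this cold-start convention makes the bias computable from
trial 1; "carry the last bias" would be the alternative). The medial-trial
probability is the double sigmoid

P_med = 1 − 0.5/(1+((bias+1)/τ₁)^S₁) − 0.5/(1+((bias+1)/τ₂)^S₂)

with τ₁ = −0.5, τ₂ = 0.5, S₁ = 30, S₂ = 12, evaluated exactly as printed
(the negative τ₁ is harmless because the exponents are even integers) and
clamped to [0, 1]. As printed, the function is strongly asymmetric:
P_med(−1) = 0 but P_med ≈ 1 for any bias above about −0.4, so the controller
corrects a lateral-favoring bias but otherwise keeps sessions almost
entirely medial. Whether a sign or τ value was misprinted cannot be
determined from the source, so the formula is implemented verbatim and the
asymmetry is documented; the session generator therefore defaults to
balanced sides (`controller_on = FALSE`).

Psychometric fits maximize the binomial likelihood of
P(right) = γ + (1−γ−λ)·Φ((x−pse)/σ) over signed displacement (lateral
positive), with box constraints (γ, λ < 0.5) and profile-likelihood 95% CIs
obtained by root-finding on the profile deviance. Perfect separation drives
σ to its lower box bound and is flagged as a boundary fit. Probe-trial
analysis reports per-class percent-right answers per session and compares
anterior vs posterior probes with a paired two-sided t-test over sessions;
inactivation analysis computes per-session Δ% correct against the control
site, tests site means against zero and Bonferroni-corrects across sites.
All tests use session-level units.

## Synthetic data: what it emulates, and what it does not

Generators return ground truth alongside the data, so every pipeline stage
is testable by parameter recovery:

* `gen_tuned_population()` builds trial tables (two movement phases per
  trial, onsets stored both in seconds and 0-based samples) and traces as a
  superposition of peak-normalized kernels scaled by Gaussian tuning. The
  phasic kernel is a difference of exponentials (50 ms rise, 800 ms decay —
  the same indicator timescale the deconvolution assumes); the tonic kernel
  is a boxcar over the hold period convolved with the same decay. Trial
  slots include 2 s of baseline and enough tail for the kernel to die out
  before the next baseline, so noiseless per-direction peaks equal the
  tuning curve exactly. A body-petal gain multiplies the peak rate whenever
  a movement ends nearer the body-origin point than it starts. Trace noise
  is additive white Gaussian (the source states no noise model; this is a
  free parameter, not a claim about the data).
* `gen_null_traces()` produces AR(1) traces with no stimulus-locked
  component and event sets with guaranteed window spacing — the null model
  for the randomization-test calibration.
* `gen_widefield_stack()` interleaves blue frames
  baseline·(1 + signal + γ·hemo) with violet frames baseline·(1 + hemo),
  where the hemodynamic time course (slow oscillation plus low-passed AR
  noise — blood-volume dynamics are smooth on the 25 ms channel offset) is
  shared between channels and the stimulus-locked signal lives in a disk
  whose center is ground truth. The default frame noise (0.1%) represents a
  trial-averaged stack (per-frame shot noise of ~1% averaged over > 80
  trials).
* `gen_stereo_scene()` poses a simple articulated forelimb over the
  workspace grid, maps it through a stored similarity transform and projects
  it through two pinhole cameras.
* `gen_behavior_session()` draws answers from a latent psychometric
  function, injects probe trials and aborts, and logs the bias and P_med
  actually used on every trial so controller behavior can be replayed.

Not emulated: biophysical spiking or networks (responses are
phenomenological), CNMF spatial footprints or raw movies with overlapping
somata, hemodynamic biophysics, lens distortion, or motor dynamics. Passing
recovery tests on these generators shows the analysis code is correct and
calibrated under the stated generative assumptions; it does not certify
performance on real recordings whose noise is non-Gaussian, non-stationary
or spatially structured.

## Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen to keep the
statistics stable: 2000 null neurons (600 s at 30 Hz, 40 events, 1999
shuffles each) for the calibration check; 150 neurons × 8 directions × 10
trials per direction per phase for the angular-shift analysis; 200 simulated
neurons for tuning recovery; 100 replicates at 500 trials per level for
psychometric coverage. The randomization test precomputes a circular
response profile per trace, making the 1999 shuffles O(events) lookups each.

## Known limitations

* The Gaussian tuning model has no baseline term; neurons with high
  untuned firing are better described with an offset, which slightly
  inflates fitted widths on such data.
* Profile-likelihood CIs for guess/lapse sit at the box bound when the true
  rates are near zero; their coverage is conservative there.
* The printed bias-controller formula corrects only one bias direction (see
  above); sessions generated with it enabled are heavily medial.
* Triangulation assumes distortion-free pinhole calibrations; with real
  lenses, undistort before triangulating.
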