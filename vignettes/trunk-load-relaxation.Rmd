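---
title: "Modeling trunk load-relaxation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trunk load-relaxation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkrelax)
```

## The measurement problem

When the lumbar spine is held in a flexed posture, the passive tissues
(discs, ligaments, facet capsules, passive muscle components) that resist
the flexion moment relax: at a constant flexion angle the resisting moment
decays over minutes.  This load-relaxation, its dependence on the flexion
angle, and the associated widening of the low-stiffness *neutral zone*
(NZ) around upright posture are of interest because reduced passive
support must be compensated by muscle activity, with consequences for
spinal loading.

A laboratory exposure has a ramp-hold-ramp structure: the trunk is flexed
at a slow constant rate (~3 deg/s) to a target angle expressed as a
fraction of the subject's flexion-relaxation (FR) angle, held there for
16 minutes while the restraining force is recorded, and returned.  The
three phases (loading, load-relaxation, unloading) yield complementary
measures:

* **Windowed relaxation statistics** — mean moment over the first and
  last 3 s of the hold give the *initial moment* and *moment drop*;
  `t90` is the time to 90% of the total drop.
* **Hysteresis loop** — the loading and unloading angle–moment curves
  enclose the dissipated energy `dE = E1 - E2`; the ratio `RE = dE/E1`
  summarises the viscoelastic state (0 purely elastic, 1 purely viscous).
* **Neutral zone** — the contiguous extent from upright posture over
  which the curve slope stays below 0.1 Nm/deg and the moment below
  7 Nm.
* **Constitutive fits** — four relaxation models fitted to the hold.

## The four relaxation models

All models are expressed in degrees and Nm (stiffness Nm/deg); no radian
conversion is performed anywhere, matching the units in which such
parameters are conventionally reported.  For a constant hold angle
$\theta_0$:

* **Standard linear solid (SLS)** — one Maxwell branch (spring $K_1$ in
  series with damper $C$) in parallel with a spring $K_2$:
  $M(t) = \theta_0\,(K_2 + K_1 e^{-t/T})$, $T = C/K_1$.
* **Prony series (Wiechert)** — $n$ Maxwell branches:
  $M(t) = \theta_0\,(K_\infty + \sum_i K_i e^{-t/\tau_i})$.  Two branches
  are the default; the branch time constants are stored sorted ascending
  so that branch labels are identifiable.
* **Schapery power law** — $M(t) = \theta_0\,(k_{eq} + c_1 t^{-c_2})$,
  with $k_{eq}$ the equilibrium stiffness.
* **Modified superposition (MSM)** —
  $M(t) = \theta_0\, k_0\, t^{-\beta}$.

The power-law forms diverge at $t = 0$, and published applications do not
pin down a time offset; both are therefore defined, evaluated and fitted
only for $t \ge 1$ s after hold onset, with the hold-onset anchor
$M(1) = \theta_0 (k_{eq} + c_1)$ (respectively $\theta_0 k_0$).  Several
variants of the two power-law models circulate in the soft-tissue
literature; the classical forms above are adopted and stated explicitly
so that fitted constants are interpretable without ambiguity.

## Synthetic ground truth: the hereditary integral

No public recordings of this protocol exist, so the package generates
them.  The generator's mechanical core, `truth_moment()`, evaluates the
response of a generalized Maxwell (Kelvin-solid) model to an *arbitrary*
angle history by a discrete hereditary integral: each Maxwell branch
moment obeys $\dot h = -h/\tau + K \dot\theta$ and is advanced by

$$h_{j+1} = h_j e^{-\Delta t/\tau} + K \tau
  \frac{1 - e^{-\Delta t/\tau}}{\Delta t}\,\Delta\theta_j ,$$

which is the exact solution when the angle is piecewise linear between
samples — the update is therefore unconditionally stable and exact for
the trapezoidal protocols used here (step histories reproduce the closed
forms to machine precision; grid halving is a no-op up to rounding).  A
non-zero first sample is treated as an instantaneous step from rest.
Negative predicted moments are clamped to zero throughout: the harness
contact is one-sided and can only push.

The generator layers the study conditions on top of this kernel:

* **Protocol** (`protocol_spec`): 3 deg/s ramps, 960-s hold, angle
  sampled at 100 Hz (IMU) and force at 1000 Hz (load cell), moment arm
  0.40 m.  Hold angles are fractions {0.30, 0.40, 0.60, 0.80, 1.00} of
  the subject's FR angle; cohort FR angles are drawn from a
  truncated-positive normal with mean 58.2 deg and SD 12.0 deg.
* **Mechanics** (`ground_truth_spec`): the default truth is a two-branch
  Prony series with time constants near 10 s and 1000 s, which produces
  the distinct fast (first 30–60 s) and slow relaxation phases seen in
  vivo.  A neutral zone of width 10 deg with residual stiffness
  0.02 Nm/deg (well below the 0.1 Nm/deg NZ criterion) is imposed by
  letting the viscoelastic element act on the angle in excess of the NZ.
  All stiffnesses scale as $e^{g\theta_0}$ with $g = 0.02$ /deg, giving
  the exponential growth of initial moment with flexion angle.
* **Noise**: independent Gaussian noise on the angle stream (SD 0.1 deg,
  IMU-grade) and the force stream (SD 0.5 N, the RMS noise scale of an
  amplified strain-gauge load cell; the instrument's true figure is not
  published, so this is configuration, not an assumption baked into the
  code).

What the generator does *not* emulate: voluntary muscle activity and its
EMG correlates, postural sway, drift or creep of the restraint, thoracic
or pelvic contributions to the measured angle, and any pre/post change in
the elastic parameters other than what relaxation itself produces.
Passing tests therefore demonstrate correctness of the analysis chain
under the stated mechanical model, not robustness to every artifact of
human data.

## Numerical and design choices

* **Stream alignment** — force (1000 Hz) is averaged onto the angle grid
  (100 Hz) with a symmetric 10-sample window whose endpoints carry half
  weight; the symmetry avoids a half-sample lag that would otherwise bias
  loading and unloading curves in opposite directions.
* **Phase segmentation** — the angle rate is estimated by central
  differences after a 1-s moving average; loading/unloading are rate
  excursions beyond ±0.5 deg/s (one sixth of the ramp rate).  The 1-s
  window is much shorter than any ramp, so breakpoints are recovered to
  ±0.5 s on clean trapezoids.  Records without a detectable rise or
  plateau raise an error and are skipped by the pipeline with a logged
  reason, mirroring discarded low-angle trials.
* **Windows** — 3-s half-open windows `[t0, t0 + 3)`, sample means (the
  choice between mean and median is not documented for this protocol;
  mean is used).  `t90` is defined on the total drop (initial − final),
  not on the absolute moment; the alternative reading of "90% drop" is
  one flag away in `summarize_relaxation()`.
* **Hysteresis loop** — curves are re-binned onto a 0.25-deg angle grid
  by within-bin averaging; energies by trapezoidal integration with
  moments floored at zero, so `E2` counts only recovered (positive) work
  and the pure-viscous limit `RE = 1` holds exactly under one-sided
  contact.
* **Neutral zone** — local slope by linear regression over a trailing
  1-deg window (extended forward to a full 1-deg span for the first
  bins, where a truncated window would be noise-dominated).  The trailing
  orientation judges each bin by the curve on its neutral side, which
  recovers constructed breakpoints to within one bin.  Pre-exposure NZ
  is measured on the loading curve and post-exposure NZ on the unloading
  curve of the same trial; both curves are exposed so the opposite
  convention is available.
* **Fitting** — bounded Levenberg–Marquardt (via **minpack.lm**) from
  8 deterministic starts whose initial time constants are log-spaced over
  `[1 s, hold]`; stiffness bounds `(0, 100]` Nm/deg, time-constant bounds
  `[0.1 s, 10 x hold]`.  Ties between starts are broken by SSE, then by
  the smaller parameter norm, so refits are reproducible.  Long segments
  are uniformly subsampled to at most 2000 points; fits are insensitive
  to this (tested).  Schapery's $k_{eq}$ is pinned to the final-window
  stiffness by default; because the final window still contains whatever
  power-law tail has not relaxed, identifiability studies with known
  ground truth should pass the true equilibrium stiffness via
  `k_eq_value`.
* **Sensitivity coefficients** — $SC = (\Delta R / \bar R) /
  (\Delta p / \bar p)$, the normalized outcome range over the normalized
  parameter range, reported as an absolute value.  The two normalizations
  found in the literature, $(\Delta R/\bar R)/(\Delta p/\bar p)$ and
  $(\Delta R/\Delta p)(\bar p/\bar R)$, are algebraically identical, so
  no switch is provided.  Outcomes are evaluated at the start of the
  relaxation window (t = 0 for the exponential models, t = 1 s for the
  power models) rather than window-averaged: point evaluation preserves
  the exact analytic zeros — any pure time-constant parameter has
  *exactly* zero sensitivity with respect to the initial moment, as does
  the SLS parallel stiffness with respect to the moment drop — whereas a
  3-s window mean would blur them by a fraction of a percent.  Window
  averaging remains available (`window_s`) for consistency studies with
  the measurement-side definition.
* **Angle trends** — cohort means are fitted with linear and exponential
  families.  Because zero flexion must give zero moment, the origin can
  be appended as a data point, and the through-origin exponential is
  parameterised $y = a(e^{bx} - 1)$ — a plain exponential $ae^{bx}$
  cannot pass through the origin.  Flat outcomes degenerate to the
  $b \to 0$ limit and are flagged rather than fitted.

## Problem sizes

The test-suite and example cohorts use 60-s holds for pipeline-level
checks (a hold long enough for the fast relaxation phase and for two 3-s
windows, while keeping a 50-trial cohort cheap) and full 960-s holds
wherever relaxation-scale quantities matter: oracle convergence, model
round trips, noisy-recovery replicates, and the model-ranking cohort.
Noisy parameter-recovery claims are made on the mean relative error over
20 seeded replicates; individual replicates of the slow Prony time
constant can wander further, which is intrinsic estimator variance at 1%
multiplicative noise over a hold that spans the slow time constant only
once.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_subjects = 4, fractions = c(0.4, 0.6, 1.0),
                       hold_duration = 60, seed = 42)
res <- run_pipeline(cfg)
head(res$outcomes)
res$comparison           # mean R^2 / RMSE per model and %FR level
res$sensitivity          # cohort-derived sensitivity table
res$trends$initial_moment_exponential
```

## Known limitations

* The generator's truth is linear-viscoelastic given the hold angle; the
  angle-dependent stiffness gain makes the *cohort* nonlinear, but within
  one trial superposition holds exactly.  Real tissue shows
  within-trial nonlinearity that none of the four fitted forms capture
  fully.
* The NZ detector assumes the curve is anchored near 0 deg; protocols
  that never pass through upright posture are rejected rather than
  extrapolated.
* Fits are per-trial; no pooling across subjects (mixed-effects
  estimation is out of scope).
* `t90` is reported only when the 90%-drop level is crossed within the
  hold; short holds leave it flagged unresolved rather than
  extrapolated.
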