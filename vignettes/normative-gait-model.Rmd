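---
title: "Predicting normative gait kinematics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting normative gait kinematics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normgait)
```

## The model

`normgait` treats a joint-angle waveform not as 101 free values but as a
small set of clinically meaningful key-points, each described by its timing
in the gait cycle, its angle, and (for reconstruction) its angular velocity
and acceleration. The modelling chain is:

1. **Discretise** each hip/knee/ankle flexion-extension waveform into its
   key-points (6, 8 and 7 respectively): extrema inside gait-event-bounded
   windows (e.g. the stance hip-extension minimum between ipsilateral foot
   strike and foot off) and angles at anchored instants (e.g. at foot
   strike, or at the middle of stance).
2. **Regress** every key-point parameter on the predictor vector
   `P = [v*, age, sex, BMI]`, where `v*` is walking speed divided by
   `sqrt(g * leg length)` (the square root of the Froude number). Predictors
   enter in raw units — years, 0/1, kg/m² — because the bundled published
   coefficients are only meaningful on those scales. Selection first
   (stepwise, p < 0.01), then a robust fit (IRLS, Tukey bisquare).
3. **Reconstruct** a continuous waveform from predicted key-point states by
   piecewise fifth-order polynomial interpolation: each segment matches
   angle, velocity and acceleration at both of its knots (six constraints,
   six coefficients), which makes the curve C²-continuous across knots. The
   cycle-end state is set equal to the cycle-start state, so consecutive
   cycles join without discontinuity in value, slope or curvature.

The central modelling assumptions are (a) that the key-point set captures
what matters clinically about the waveform — the bundled sets keep the
discretise-reconstruct error below 2°, the level below which no clinical
consequence is expected; and (b) that within the calibration range of
dimensionless speed (about 0.2–0.7) each key-point parameter responds
*linearly* to each predictor. Below 0.2 walking degenerates towards a
sequence of postures and above 0.7 the walk–run transition begins, so
predictions outside that envelope are flagged
(`attr(x, "speed_extrapolated")`) rather than refused.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `alpha` | `stepwise_select()` | 0.01 | retention threshold for a predictor; entry and removal use the same value |
| `tuning` | `robust_fit()` | 4.685 | bisquare constant, 95% Gaussian efficiency; residual scale is MAD/0.6745 |
| `tol`, `max_iter` | `robust_fit()` | 1e-8, 100 | IRLS convergence on max absolute coefficient change |
| `g` | speed normalisation | 9.81 m/s² | configurable; only the product `g * leg_length` matters |
| timing threshold | `classify_clinical()` | 3% gait cycle | a four-frame event-detection window at 120 Hz over a 1.10 s cycle |
| angle bands | `classify_clinical()` | 2° / 5° | below 2° no consequence; 2–5° consider; above 5° may mislead interpretation |
| sweep design | `sweep_predictor()` | 15 values (2 for sex), others at medians (`v* = 0.45`, age 38, sex 1, BMI 24) | isolates one predictor's contribution; medians are configurable because the reference study's exact medians are not published |
| `bin_width` | `loocv()` | 0.05 `v*` | granularity of the speed-binned summary |

Timings live on the 1..101 sample scale (sample k ↔ (k−1)% of the cycle);
angles in degrees; angular velocity and acceleration in degrees per
(% gait cycle) and its square.

## Numerical choices

* **Window resolution.** Fractional anchors ("middle time", "one quarter")
  are linear interpolations between their two events, rounded half-up to
  the nearest sample; windows are inclusive at both ends. Extremum ties
  take the first occurrence, which is deterministic and order-stable.
* **The HIS5 window.** The swing hip-flexion maximum is searched between
  one quarter and three quarters of the foot-off-to-foot-strike interval;
  the two printed fractional anchors are read as the window bounds.
* **Derivatives at extraction** are central finite differences with
  periodic wrap (period 100 samples), consistent with the imposed
  cycle-continuity constraint.
* **Quintic segments** are solved as a 6×6 linear system in a local
  coordinate `u = (t - t_left)/(t_right - t_left)`; derivative constraints
  are rescaled by the segment width. This keeps the system conditioned for
  short and long segments alike; the unit tests verify recovery of known
  generating polynomials to 1e-8 relative.
* **Derivative completion.** The bundled published table models timing and
  angle only. Before reconstruction, velocity and acceleration at each
  predicted key-point are taken from a periodic cubic spline through the
  predicted (timing, angle) knots; a user table that models the derivative
  parameters overrides this.
* **Timing ordering repair.** Extrapolation at extreme predictor values can
  invert neighbouring predicted timings; `repair_timings()` enforces the
  schema order with a minimum one-sample separation (endpoints pinned at 1
  and 101) and warns when it had to act.
* **Stepwise degeneracy guards.** On noiseless data the selected model fits
  to machine precision, making further partial-F statistics 0/0; entry
  stops once the residual sum of squares falls below 1e-14 of the total,
  and an indeterminate removal test counts as "not significant". The
  robust fit likewise short-circuits to the OLS solution when the residual
  MAD is at numerical zero.
* **VAF** is defined as `100 * (1 - var(y - yhat)/var(y))`, which is
  insensitive to a constant offset; R² is the squared Pearson correlation.
  Both are reported as `NA` (flagged, not silently zeroed) for constant
  inputs.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the *statistical structure* of the
reference database: 54 subjects (about 30/54 male), heights near
1.74 ± 0.10 m, BMI 17–31 kg/m², five speed conditions per subject (three
imposed bands at 0.1–0.4, 0.4–0.8 and 0.8–1.2 m/s, then spontaneous
~N(1.3, 0.15) and maximal ~N(1.9, 0.2) m/s), five trials per condition, and
key-point parameters drawn from the published equations plus Gaussian noise
scaled by each equation's published RMSE. Choices the study does not pin
down and that were fixed here once: the age distribution is a truncated
normal on [19, 67] with location 35.21 so that its truncated mean equals
the study's 37.9 years (matching the reported SD of 13.7 as well is
mathematically infeasible under truncation at those bounds — the generated
SD is ≈10.8); the slowest band is floored at 0.1 m/s because near-zero
speeds are no longer gait; leg length is 0.53 × height with ~1 cm
individual variation; the spontaneous/maximal speed distributions are
standard healthy-adult values. All of these are visible in
`synth_config()` and `sample_population()`.

Noise is injected at the *key-point-parameter* level, so the regression
stage's assumptions hold exactly in synthetic data; an optional smooth
band-limited waveform-level noise (`wf_noise_sd`, ≤6 harmonics per cycle)
stresses the discretise-reconstruct path instead. What passing tests on
this generator demonstrate is therefore *internal* correctness — parameter
recovery, fold hygiene, reconstruction fidelity — not external validity on
motion-capture data, which additionally carries soft-tissue artefact,
marker-placement error, within-subject correlation between trials, and
non-Gaussian residuals.

## Design decisions on genuinely open points

* Every supplied trial row is one regression observation; left/right cycles
  and repeated trials are pooled without random effects. This matches the
  bundled table's construction and keeps the fitted object a plain
  coefficient table.
* The stepwise removal threshold equals the entry threshold (0.01): only a
  retention criterion is published, and an asymmetric default would be an
  invisible extra assumption.
* Cycle-boundary timings are emitted as constants (samples 1 and 101)
  rather than fitted: they are fixed by the cycle normalisation itself.
* Speed conversions between m/s and dimensionless units are left to the
  caller (no canonical leg length is assumed), so `contribution_range()`
  requires an explicit range for the speed predictor while defaulting to
  the study ranges for age (19–67) and BMI (17–31).
* The hold-out unit in `loocv()` is the subject, never the trial: all of a
  subject's trials leave the training set together.

## Problem sizes used by the test suite

The suite exercises reduced but structurally faithful instances: parameter
recovery on 20–54 synthetic subjects (exact to ~1e-13 relative on noiseless
data), leave-one-out validation on 8–10 subjects, the reconstruction study
on 50 cycles per joint, and 1000 random instances for the quintic-segment
oracle. One caveat found while sizing these runs: with about seven or fewer
training subjects the subject-level predictors (age, sex, BMI) can be
nearly collinear across the tiny population, and stepwise selection may
stall on a near-exact wrong predictor subset. From ten subjects upward
recovery is exact in every fold.

## Known limitations

* Linearity is assumed within the 0.2–0.7 dimensionless-speed envelope;
  outside it predictions extrapolate and are only flagged.
* The bundled table covers sagittal hip, knee and ankle angles of healthy
  adults; no frontal/transverse planes, no kinetics or EMG, no pathological
  gait, no children.
* Gait events are inputs, not detected from kinematics.
* The published velocity/acceleration equations are not bundled (they were
  published as supplementary material only); the periodic-spline completion
  stands in for them and user-supplied derivative tables take precedence.
* C3D ingestion is out of scope; the package operates downstream of motion
  capture on plain CSV/JSON.
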