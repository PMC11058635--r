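---
title: "The Bayesian participant model: simulation and inverse analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian participant model: simulation and inverse analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contpsych)
```

## The task and the model

`contpsych` models a two-variable continuous-correction experiment.  The
computer drives one stimulus variable — in the motivating case the
direction `x` of a moving background, in degrees clockwise from vertical —
as a Gaussian random walk, and the participant continuously adjusts a
second variable, the target direction `y`, so that the target *appears*
to move vertically.  Because a moving background induces an illusory
motion component in the target (induced motion), the nulling value of `y`
traces out the perceptual coupling between the two variables.  Continuous
tasks buy enormous data rates (about 2400 analysed samples per two-minute
session here) at the price of two extra noise sources: stimulus
uncertainty from the random walk and response variability from the
continuously engaged action system.  The package implements both the
generative model of such a participant and the inverse analysis that
strips those two noise sources back out.

The generative agent has three stages per 50 ms update:

* **Sensation.**  Noisy sensory copies `X = x + omega` and `Y = y + psi`
  are combined with internal predictions by constant-gain filters,
  `x_hat <- (1 - k_x) x_hat + k_x X` and
  `y_hat <- (1 - k_y)(y_hat + a) + k_y Y`, where `a` is the previous
  intended action.  The gain is the fixed point of the scalar Kalman
  variance recursion for a random-walk state,
  `k = (-r + sqrt(r^2 + 4r))/2` with `r` the ratio of process to
  observation variance (`steady_state_gain()`).  The agent assumes
  stationary noise throughout a session, so the gain is constant rather
  than time-varying; `constant_gain_filter()` agrees with a grid-based
  sequential Bayes oracle once the exact gain recursion has converged.
* **Perception.**  The perceived deviation of the target from vertical is
  formed in horizontal-component space, where the induced-motion model is
  linear: `sin(y_tilde) = sin(y_hat) - beta * sin(x_hat) + d`.  `beta` is
  the coupling strength, `d` a constant horizontal offset capturing any
  bias in the participant's subjective vertical.  Components outside
  [-1, 1] are clipped before the arcsine and counted.
* **Action.**  A unit-mass damped spring drives the perceived deviation to
  zero: `v <- v + dt (b e - c v)` with `e` the sign-flipped perceived
  deviation sensed `delta_t` seconds earlier (integer-sample delay,
  linearly interpolated for fractional lags), and the realised step is
  `dt v` plus Gaussian motor noise `lambda`.

## Default parameters and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `sigma_lambda2` | 0.22 | deg^2/update | motor noise variance estimated for participant data |
| `sigma_omega2`, `sigma_psi2`, `sigma_phi2` | 1.6 | deg^2 | training-session estimate, shared across channels by assumption |
| `b` | 0.375 | 1/s^2 | spring constant fitted to a participant's training step responses |
| `delta_t` | 0.4 | s | reaction lag estimated from training data (0.41 s, rounded to the 0.05 s grid) |
| `beta` | 0.71 | — | induced-motion strength of a reference participant |
| `speed` | 6 | deg/s | global stimulus speed |
| `dt` | 0.05 | s | 20 updates/s; session 130 s with the first 10 s discarded |
| `sigma_mu` | 2 | deg/update | see below |
| `c` | 0.4 | 1/s | see below |

Two defaults are the package's own modelling choices:

* **Walk step `sigma_mu = 2`.**  The step size of the background walk is
  not published.  The experimental procedure requires candidate walks to
  cover the whole 0–90 degree quadrant (all nine analysis bins) within a
  single session, and `gen_session_walk()` redraws candidates until one
  does.  At 20 updates/s over 120 analysed seconds, a reflected walk with
  2 degree steps covers the quadrant within a handful of candidates;
  appreciably smaller steps essentially never do.
* **Damping `c = 0.4`.**  Damping constants fitted to 5 s average step
  responses are near zero (0.008 and 0.024 for the two reference
  participants) because a 5 s window barely constrains damping.  Those
  values cannot be used to *simulate* a closed loop: with a 0.4 s reaction
  lag, delay-induced instability sets in below roughly `c = 0.15` at
  `b = 0.375`, and even without lag the loop would ring for minutes.  The
  simulator therefore defaults to a damping ratio of about one third
  (`c = 0.4`), which keeps the delayed loop stable (about 23 degrees of
  phase margin) while still producing the marked overshoot participants
  show in training step responses.  The near-zero published values remain
  fully supported in the *analysis* direction (training fits and
  inversion), which does not run the loop forward.

## Training analysis

`simulate_training()` runs the agent against a blob that steps 10 degrees
clockwise or anticlockwise with equal probability every 5 s for 130 s.
`extract_step_responses()` cuts the target trace into one segment per
step, re-zeroes each to the pre-step target value, rectifies the sign and
averages; `fit_spring()` then least-squares fits the closed-loop lagged
spring response to the average (Nelder-Mead over `log b`, `log c` and the
lag, from a small multi-start grid with a polishing restart).  The
reaction lag is also estimated non-parametrically as the first 5%-of-step
departure from baseline, and both estimates are reported, since it is not
obvious whether a fitted or a threshold lag is the better analogue of
published lag values.  `synthetic_step_session()` provides the
rest-per-epoch idealisation — every epoch replays the deterministic
single-step response — used as the exact oracle for fitter round-trip
tests; it exists because weakly damped springs never settle between real
epochs, so a free-running noiseless agent would not produce identical
segments.

`estimate_endpoint_variance()` implements the published sensory-variance
estimator (sample variance of the blob-target mismatch at each step end).
Under the package's own generative conditions this estimator is strongly
upward-biased — with an underdamped spring the step endpoints land
mid-overshoot, so the mismatch reflects dynamics, not just sensory noise.
It is retained as specified; the analysis gains take their variances from
the configuration, not from this estimate.

## The inverse pipeline

`estimate_states()` reproduces the participant's internal estimates from
the raw data: `x_hat` by constant-gain filtering of `x`, and `y_hat` by
the same filter with the *observed increments* of `y` as the action
input — the analysis cannot know intended actions, so realised increments
(intended action plus motor noise) stand in, and the small `k_y` is
exactly how motor noise enters.  `x* = x_hat`.

`invert_action()` recovers the perceived deviation that drove the
actions.  The spring difference equation inverts exactly:
`e[t - lag] = (vdot[t] + c v[t-1]) / b` with `v` the first difference of
`y_hat`.  Exact inversion amplifies motor noise quadratically with
frequency, so the raw inverse is smoothed with a zero-phase second-order
Butterworth low-pass before being re-shifted forward by the lag.  Two
numerical choices matter here:

* **Cutoff.**  The default cutoff is 1.6 times the spring's natural
  frequency `sqrt(b)/(2 pi)` (about 0.16 Hz at the default `b`).  The
  action data carry information about the error signal only out to the
  resonant shoulder of the weakly damped loop; beyond it the inverse is
  noise.  The factor is configurable (`cutoff_hz`), and `Inf` gives the
  exact inverse, appropriate for noiseless data.
* **Two bands.**  Above the spring band the perceived deviation is
  dominated by stimulus-driven jitter — the filtered background walk
  passes almost unattenuated into `x_hat` and hence into the perception —
  and that component is invisible in the action data.  It is, however,
  predictable from `x_hat`: `finalize()` reconstructs it as the high-band
  part of `-asin(beta * sin(x_hat))`, with `beta` taken from a first-pass
  fit to the low-band-corrected series, and adds it to the low-band
  inverse.  Smoothing and re-alignment are ordered so that the filter
  never sees the lag-shift padding (a lesson encoded in a regression
  test), and the filter padding itself is mirror reflection, because
  pivoting padding on a single noise-dominated endpoint sample injects a
  large edge transient.

`finalize()` assembles `y* = y_hat - y_tilde_hat` over the post-discard
window and reports three lags: the group delay of the background filter
`dt (1 - k_x)/k_x`, the action lag (fitted reaction lag plus the spring's
half-rise time), and the residual cross-correlation lag between `x*` and
`y*`, which is zero when the model accounts for all the lag in the data.

## Adaptation

Long exposure to a net rightward motion component desensitises the
corresponding channel.  The linear accumulation model subtracts
`q * sum(h)` from the horizontal component `h = speed * sin(y)`, with the
running sum taken per update step *including the current one* — the
convention that reproduces the worked example (6 deg/s rightward for 1 s
at `q = 1e-4` perceived as 5.988 deg/s, a 0.2% change).  In the agent the
same correction is applied at the sensation stage of the dependent
channel.  `optimize_q()` recovers `q` by Brent search on [0, 1e-2],
driving the regression of de-adapted target components on background
components through a target intercept (0 by default; a nonzero target
expresses a constant perceptual bias).  Because Brent never returns an
exact endpoint, the boundary `q = 0` is explicitly preferred whenever it
does at least as well — unadapted data should report a zero rate, not a
numerically tiny one.  `de_adapt()` and `re_adapt()` are exact inverses
in the absence of clipping.

## Model statistics

`fit_model()` fits `sin(y) = beta sin(x) + h0` by least squares (the
model is linear in horizontal-component space), reporting `beta`, the
offset in both conventions (`d = -h0` unitless, `offset_deg = asin(h0)`
in degrees), `R^2` on the raw pairs, `AIC = n log(RSS/n) + 2K` with
`K = 3`, and the mean square distance between per-bin means of the data
and identically binned model predictions over nine equal-width bins.
Only AIC *differences* are meaningful (the absolute values depend on an
arbitrary convention), and `compare_fits()` applies the usual rule that a
drop of at least 2 marks a real improvement.  Published absolute AIC
values from participant data use an unstated convention and are not
reproducible; group-level statistics across participants are out of
scope.

## What the generator does and does not emulate

The synthetic data reproduce the structural features the analysis relies
on: a reflected Gaussian-step background walk with coverage selection, a
Bayes-optimal constant-gain observer with stationary noise, the
horizontal-component perception rule, a lagged underdamped spring with
additive motor noise, and linear-accumulation adaptation at the sensation
stage.  They do not emulate stimulus rendering, eye movements, fatigue or
attention drift, non-stationary noise, nonlinear motor dynamics, or
exponential adaptation time courses.  Tests passing on this synthetic
world show that the analysis correctly inverts its own generative
assumptions at realistic noise levels and sample sizes — not that those
assumptions are true of any given human participant.

Test and acceptance runs use the study-scale problem sizes throughout:
130 s sessions (2600 samples, 2400 analysed) for correction sessions,
250 s for the symmetric-walk adaptation analyses, 24 analysed training
steps, grids of 3 coupling strengths, and 10-session batteries for the
variance-reduction statistics.

## Known limitations

* The lag decomposition reconstructs the published three-way split from
  the filter group delay, the spring rise time and a residual
  cross-correlation; published per-participant lag values (for example a
  1.51 s estimation lag, implying a far smaller `k_x` than the training
  variances imply) are not reproducible from the stated variances, and
  the tiny published `k_y = 0.00052` likewise implies a gain convention
  that the training-variance route does not yield.
* The endpoint-variance estimator inherits the dynamical bias described
  above.
* `optimize_q()` assumes the intercept is monotone in `q` over the search
  bracket, which holds for sessions with nonzero net accumulated
  exposure; a session with exactly balanced exposure leaves `q` poorly
  identified.
* Walk boundary handling is reflection; clamping or resampling at the
  boundary would slightly change the stationary distribution near the
  range edges.
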