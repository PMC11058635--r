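# contpsych

Simulation and analysis of **two-variable continuous psychophysics**
experiments, built around a generative "Bayesian participant" model.

In a continuous-correction experiment the computer randomly perturbs one
above-threshold stimulus variable while the participant continuously
adjusts a second one to null a perceptual deviation.  The motivating case
is induced motion: a background moving in direction *x* (degrees clockwise
from vertical) lends the target an illusory opposite motion component, and
the participant steers the target direction *y* so that it *appears*
vertical.  A two-minute session yields thousands of (x, y) samples — but
corrupted by stimulus uncertainty and by action-system variability that
trial-based designs do not have.  This package is for experimentalists who
want that data rate without giving up trial-grade data quality.

## The model

The participant is modelled per 50 ms update as

* **Sensation** — constant-gain Bayes-optimal filtering of noisy sensory
  copies of x and y, with the steady-state random-walk Kalman gain
  k = (−r + √(r² + 4r))/2, r = σ²(process)/σ²(observation);
* **Perception** — an induced-motion rule, linear in horizontal
  components: sin ỹ = sin ŷ − β sin x̂ + d, where ỹ is the perceived
  deviation from vertical, β the coupling strength and d a constant bias;
* **Action** — a lagged damped spring driving ỹ to zero,
  v ← v + dt(b·e − c·v) with e = −ỹ(t − Δt), plus Gaussian motor noise.

The analysis pipeline inverts this model: it filters raw (x, y) into the
participant's internal estimates (x̂, ŷ), inverts the spring equation
(with band-limited regularisation) to recover ỹ, and forms the "ideal"
series **x\* = x̂**, **y\* = ŷ − ỹ**, from which β and d are estimated by a
linear fit in horizontal-component space.  A linear-accumulation
adaptation model (subtract q × the running sum of horizontal components)
can be estimated and removed first.  Everything — stimulus walks,
training-session system identification of (b, c, Δt), the agent, the
inverse pipeline, binning/fit statistics, and a CLI — is included; all
test data are simulated in-process.

## Worked example

```r
library(contpsych)
cfg <- run_config(seed = 1)          # defaults: beta = 0.71, 130 s session
out <- run_pipeline(cfg)
print(out$fit_raw)
print(out$fit_final)
print(out$comparison)
```

```
<model_fit> beta = 0.6612, offset = 0.84 deg (d = -0.01466)
  R^2 = 0.6605, AIC = -8234, msd = 8.806 deg^2 (n = 2400)
<model_fit> beta = 0.7129, offset = 0.209 deg (d = -0.003648)
  R^2 = 0.9496, AIC = -1.333e+04, msd = 1.097 deg^2 (n = 2400)
<fit_comparison> raw -> processed
  delta R^2 = +0.2892, delta AIC = +5094 (significant)
  delta msd = +7.709 deg^2; mean per-bin SD 7.94 -> 4.39 deg
```

Reading this: the session was simulated with a true coupling β = 0.71.
The raw regression of sin y on sin x is attenuated to 0.66 by tracking
lag, while the fit to the finalized series recovers 0.713; the mean
per-bin standard deviation of the target direction drops from 7.9° to
4.4° after processing, R² rises from 0.66 to 0.95, and the AIC drop is
far beyond the conventional significance change of 2.

A command-line front end wrapping the same functions is installed at
`inst/cli/bp.R` with subcommands `simulate`, `fit-training`, `deadapt`,
`analyze`, `fit-model` and `run` (exit codes: 0 ok, 2 config error,
3 data error, 4 fit failure).

See the vignette (`vignettes/bayesian-participant.Rmd`) for the model
assumptions, parameter defaults and their rationale, and numerical
design choices.

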