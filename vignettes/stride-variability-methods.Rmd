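---
title: "Estimating the metabolic cost of stride-to-stride variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the metabolic cost of stride-to-stride variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human walking is never perfectly periodic: stride period, joint kinematics
and ground reaction forces (GRFs) fluctuate from stride to stride because of
sensory and motor noise and the feedback corrections that keep walking
stable. Simulation-based estimates of walking metabolic cost usually start
from a *single* representative stride — either one stride picked from a
recording, or an "averaged gait pattern" built by averaging the signals of
several strides at each gait-cycle fraction. Both choices interact with the
variability. `stridecost` implements three estimators of a trial's effort
rate and the machinery to compare them:

* **Method 1** — cost of one randomly selected stride.
* **Method 2** — cost of the averaged gait pattern: strides are mapped onto
  a common 0–100% gait-cycle grid, averaged pointwise, and the average is
  mapped to the mean stride period. This is equivalent to zeroing out the
  variability.
* **Method 3** — the mean of the per-stride costs, which retains the
  variability fully and serves as the reference.

For a cost functional that is the time average of a convex pointwise
function of the signals — such as the torque-squared effort
$\dot E = \tfrac{1}{T}\int_0^T \sum_j a_j \tau_j(t)^2\,dt$ — Jensen's
inequality forces method 2 to underestimate method 3:
$f\!\big(\tfrac{p_1+p_2}{2}\big) \le \tfrac{f(p_1)+f(p_2)}{2}$ pointwise at
every gait-cycle fraction, hence after averaging over the cycle. The gap is
the modelled metabolic cost of the variability itself. Method 1 carries no
systematic bias but a stride-to-stride random error that can be an order of
magnitude larger than the method-2 bias. Because the variance of an
N-stride mean shrinks like $1/N$ for roughly independent strides, method 3
with moderate N is the natural gold standard
(`variance_scaling_experiment()` verifies the $1/N$ law empirically).

## Pipeline and numerical choices

**Filtering.** `lowpass_filter()` applies a Butterworth low-pass
forward–backward (`signal::filtfilt`), so the effective magnitude response
is the squared design response and the phase is exactly zero — event times
derived from filtered signals are unbiased. Defaults: 6 Hz cutoff (the
conventional gait choice; it removes impact transients and soft-tissue
ringing) and order 4 per pass. The order and pass direction are package
defaults, not claims about any particular dataset: only the cutoff is
conventional enough to fix.

**Event detection.** A heel strike is the first sample at or above the
30 N vertical-GRF threshold after at least one sample below it; candidate
events closer than 0.4 s (a lower bound on plausible stride periods) to the
previous accepted event are discarded. Reporting the first at-or-above
sample means detected times sit within one sample *after* the continuous
crossing, a convention the tests rely on. Swing is defined by the same
threshold, and `zero_swing_grf()` zeroes all GRF components of a foot
wherever its vertical force is sub-threshold.

**Segmentation.** A stride spans one left heel strike to the next. Stride
k keeps the samples from event k through event k+1 *inclusive*, so
neighbouring strides share their boundary sample and durations add up
exactly to the heel-strike span.

**Time normalization and the common-grid evaluation.** Strides are
resampled by linear interpolation onto a uniform 101-point gait-cycle grid
(0, 1, …, 100%); linear interpolation is monotone and artifact-free at
this density, and 101 points make both endpoints explicit.
`estimate_methods()` evaluates *all three* estimators on this grid
representation — per-stride costs included — rather than computing
per-stride costs on the raw samples. This is deliberate: with a common
discretization, differences between the estimators reflect stride-to-stride
variability only, not quadrature differences between grids. It also makes
two exact properties hold to machine precision, which the tests assert at
1e-8: with identical strides all three methods coincide, and for
time-averaged convex costs method 2 can never exceed method 3 (the
inequality holds pointwise at every grid fraction). Quadrature is
trapezoidal throughout; its $O(h^2)$ error at 100 Hz is orders of magnitude
below the effects studied.

**Method-3 weighting.** Per-stride costs are already time-averaged rates,
so method 3 defaults to their unweighted arithmetic mean. A
duration-weighted variant (total energy over total time) is available via
`duration_weighted = TRUE`; the two coincide whenever stride durations are
equal.

## Cost models

**Torque-squared** (`torque_cost_model()`): $\dot E = \tfrac{1}{T}\int
\sum_j a_j\tau_j^2\,dt$ with all $a_j = 1$ by default (the illustrative
convention). Strictly convex in the torque trajectory, hence the cleanest
setting for the Jensen analysis; invariant to torque sign and quadratic
under scaling.

**Muscle heat rates** (`muscle_params()`, `umberger_heat_rates()`,
`muscle_cost_model()`): the classic decomposition of a muscle's energy
liberation rate into fibre work rate $\dot W$ plus activation, maintenance
and shortening/lengthening heat rates,
$\dot E = \dot W + \dot h_A + \dot h_m + \dot h_{sl}$. The implementation
uses the published mixed fibre-type coefficient tables: combined
activation–maintenance base rate $128 f + 25$ W kg⁻¹ (fast-twitch fraction
$f$), split 40% activation / 60% maintenance with the maintenance share
modulated by a Gaussian force–length factor (width parameter 0.45) above
optimal fibre length; effective activation $A = u$ when excitation exceeds
activation and $(u+a)/2$ otherwise, entering as $A^{0.6}$
(activation/maintenance), $A^2$ (shortening heat) and $A$ (lengthening
heat); shortening coefficients $100/v_{max}^{slow}$ and $153/v_{max}$ with
$v_{max}^{slow} = v_{max}/2.5$ and slow-twitch velocity saturation; and a
lengthening coefficient four times the slow shortening coefficient. Fibre
work rate is $-(\text{active force})\times(\text{fibre velocity in m/s})$.
Variant flags default to `clamp_total_nonnegative = TRUE` (a muscle cannot
bank free energy from negative work), `include_basal = FALSE`, and
`aerobic_scale = 1.5`, matching common musculoskeletal-probe defaults; all
are configurable because published probe settings vary. Muscle-state
trajectories are *inputs* here — no excitation–activation or tendon
dynamics are solved; in the intended workflow those come from an external
muscle-control solution, and in this package from
`generate_muscle_states()`.

A caveat the tests respect: the $A^{0.6}$ activation/maintenance term is
*concave* in activation, so the total rate is convex in activation only
away from the isometric, low-activation regime — where shortening heat
($\propto A^2$) and work (linear in force) dominate. The Jensen-direction
guarantee is therefore stated and tested for the torque-squared model; for
the heat-rate model the underestimation is expected but not a theorem.

## The synthetic gait generator

`generate_gait_trial()` stands in for a treadmill recording. Its defaults
are fixed study conditions, chosen once: 100 Hz sampling, 1.1 s base stride
period, 5 strides per trial (plus one extra repetition so n+1 heel strikes
exist), amplitude variability SD 5% of the time-varying part of each
channel, stride-period jitter SD 0.02 s, and additive measurement noise of
0.25° (angles), 0.5 N·m (moments) and 2 N (GRFs) — magnitudes typical of
steady treadmill gait and motion-capture/force-plate chains. Channel
shapes are low-order Fourier templates (≤ 3 harmonics here) with
textbook-like waveforms, plus a double-bump vertical GRF that is exactly
0 N through a swing window covering 38% of the cycle and rises through
30 N exactly once per stride; the continuous crossing instants are returned
as ground truth. Period jitter dilates each stride's template uniformly in
time — exactly the kind of variability that gait-cycle normalization
undoes — and amplitude variability scales the time-varying part only, so
GRF swing phases stay at zero.

What the generator does *not* emulate: biomechanical consistency between
moments and GRFs (no inverse dynamics constraint), asymmetry between legs,
non-stationarity (drifting speed or fatigue), correlated stride-to-stride
structure, and marker-level artefacts. Passing tests therefore demonstrate
the estimator algebra and the direction and scaling of the
variability-induced bias — not the bias magnitude to be expected in any
particular human dataset, which depends on the real variability structure.

## The inverted-pendulum walker

`simulate_walk()` reproduces the cost-of-variability effect in a minimal
dynamical model: a point-mass, massless-leg compass walker in
nondimensional units ($m = g = \ell = 1$). Stance obeys
$\ddot\theta = \sin\theta$, conserving $\tfrac12\dot\theta^2 + \cos\theta$;
the step-to-step transition applies a push-off impulse $P$ along the
trailing leg followed by a heel-strike impulse along the new leg, giving
$v^+ = v^-\cos 2\alpha + P\sin 2\alpha$, push-off work $P^2/2$ and
heel-strike loss $\tfrac12(v^-\sin 2\alpha - P\cos 2\alpha)^2$ at
inter-leg angle $2\alpha$ (step length $s = 2\sin\alpha$). Per-step cost is
push-off work plus a swing cost $c_{sw}(1/T_{step})^q$ with $q = 3$;
$c_{sw} = 0.0176555362$ was calibrated once so that the energy-optimal gait
at speed 0.4 has step length 0.6 leg lengths (human-like proportions), and
with it the optimal step length grows with speed as in human walking.

`find_nominal_gait()` minimizes cost per unit time over period-1 gaits at
the target speed; periodicity pins the push-off at $P = v^-\tan\alpha$, so
the search is one-dimensional in step length (golden-section `optimize`,
inner `uniroot` on the mid-stance speed meeting the speed constraint to
1e-6). The feedback controller senses the mid-stance speed and adjusts
push-off and step length linearly; default gains are the minimum-norm pair
that deadbeats the linearized one-step speed map (partials by central
differences at the nominal gait), so a small perturbation is corrected in
a single step. Sensory noise perturbs the *sensed* speed, motor noise the
*commanded* push-off and step length; three Gaussian draws per step come
from one seeded stream in fixed order, making runs bit-reproducible.
Commands outside the admissible step-length interval are clipped and
counted; a step that cannot pass mid-stance (or is knocked backward) is a
fall — recorded, reset to the nominal state, and excluded from cost
averages, with `n_falls` reported so contaminated sweeps can be discarded.

Two implementation routes coexist deliberately: `integrate_stance()`
integrates the stance ODE with event detection (`deSolve::lsodar`) and is
the trajectory-level operation, while the step loop propagates speeds
through the conserved energy and stance times through fixed 40-node
Gauss–Legendre quadrature. A test pins the two against each other at 1e-8.
The fast route is what makes the noise sweeps (two modes × 5 noise levels ×
2000 steps × 10 seeds) a matter of seconds.

`noise_sweep()` runs one simulation per noise level with a fresh sub-seed
per level and normalizes mean cost rate and per-step cost SD by the
deterministic zero-noise baseline, so the zero row is exactly (1, 0).

## Statistics

`paired_method_test()` is the standard paired t on per-trial method-2
vs method-3 costs, reported two-sided with the mean percent difference ±
standard error. `regress_error_on_speed()` is pooled OLS of percent error
on speed — a deliberate simplification (no participant random effects).
No multiple-testing correction is applied. `jensen_gap()` exposes the
convexity diagnostic directly, and `variance_scaling_experiment()` checks
the $1/N$ law by resampling independent stride sets per N (defaults: N ∈
{1, 2, 5, 10, 20}, 2000 resamples) and reporting the log–log slope of
variance against N.

## Problem sizes and limitations

The shipped tests and the acceptance script use desk-scale sizes chosen as
the package's own defaults: 5-stride trials, 100-trial property loops,
2000-step walks, 2000-resample variance experiments. Known limitations:
the generator's independence between strides makes the $1/N$ law exact by
construction, whereas real gait has weak stride-to-stride correlations;
the heat-rate model's coefficients follow the published tables but probe
settings in the literature vary, so absolute W values should be read as
model output, not calorimetry; and the walker is a structural
reproduction — its noise levels and costs are nondimensional and are not
fit to any dataset.
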