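# stridecost

Tools for quantifying how stride-to-stride variability biases
simulation-based estimates of walking metabolic cost.

Walking is quasi-periodic: stride period, joint kinematics and ground
reaction forces fluctuate from stride to stride. Metabolic-cost pipelines
that reduce a recording to a single representative stride interact with
this variability in two different ways, and `stridecost` measures both.
Given a multi-stride trial it compares three estimators of the effort rate:

1. **method 1** — the cost of one randomly chosen stride;
2. **method 2** — the cost of the *averaged gait pattern*: strides mapped
   to 0–100% of the gait cycle, averaged pointwise at each cycle fraction,
   and remapped to the mean stride period;
3. **method 3** — the mean of the per-stride costs (the reference, which
   retains the variability fully).

For a cost that is the time average of a convex function of the signals,
such as the torque-squared effort

  Ė = (1/T) ∫₀ᵀ Σⱼ aⱼ τⱼ(t)² dt,

Jensen's inequality — f((p₁+p₂)/2) ≤ (f(p₁)+f(p₂))/2 — makes method 2 a
systematic *underestimate* of method 3; the gap is the modelled metabolic
cost of the variability itself. Method 1 is unbiased but noisy, with a
variance that shrinks like 1/N when averaged over N strides.

The package provides:

* reading/writing of gait time-series in a headered tab-delimited storage
  dialect and CSV (`read_gait_storage()`, `write_gait_storage()`);
* zero-phase Butterworth filtering, 30 N heel-strike detection, and stride
  segmentation (`lowpass_filter()`, `detect_heel_strikes()`,
  `segment_strides()`);
* gait-cycle normalization, pattern averaging and the three-method
  comparison (`time_normalize()`, `average_gait_pattern()`,
  `estimate_methods()`);
* two effort models: torque-squared (`torque_cost_model()`) and a muscle
  heat-rate energetics model decomposing Ė = Ẇ + ḣ_A + ḣ_m + ḣ_sl
  (`umberger_heat_rates()`, `muscle_cost_model()`);
* a synthetic gait and muscle-state generator with controllable
  amplitude/period/measurement variability (`generate_gait_trial()`,
  `generate_muscle_states()`);
* a feedback-controlled inverted-pendulum walker with sensory and motor
  noise (`simulate_walk()`, `noise_sweep()`, `find_nominal_gait()`);
* the comparison statistics: percent errors, paired t-tests, error-vs-speed
  regression, Jensen-gap diagnostics and the 1/N variance-scaling
  experiment (`paired_method_test()`, `jensen_gap()`,
  `variance_scaling_experiment()`).

See the vignette (`vignettes/stride-variability-methods.Rmd`) for the
models, assumptions and numerical choices.

## Worked example

```r
library(stridecost)

# a synthetic 5-stride treadmill-style trial with typical variability
cfg <- synthetic_gait_config(n_strides = 5, seed = 42)
gen <- generate_gait_trial(cfg)

trial   <- filter_trial(gen$trial)                       # 6 Hz zero-phase
ev      <- detect_heel_strikes(trial$channels$grf_vy_r,
                               trial$sampling_rate)      # 30 N threshold
strides <- segment_strides(trial, ev, n_strides = 5, start_index = 0)

estimate_methods(strides, torque_cost_model(), rng_seed = 7)
#> <method_comparison>
#>   per-stride costs: 2992.5, 2694.7, 3075.7, 2702.2, 2944.3
#>   method 1 (random stride 2): 2694.66  (-6.497%)
#>   method 2 (averaged pattern): 2878.5  (-0.117%)
#>   method 3 (mean of costs):    2881.88  (reference)
```

The per-stride costs (in (N·m)², since all joint coefficients default
to 1) spread over ±7% around their mean: picking a single stride (method 1)
happened to land 6.5% low here. The averaged gait pattern (method 2) is
below the reference — by Jensen's inequality it always is for this convex
cost — and the −0.117% gap is the modelled cost of this trial's
variability.

The inverted-pendulum walker shows the same effect mechanistically: adding
motor noise to push-off and foot placement raises the mean cost of walking
above the no-noise baseline, and the per-step cost SD grows with it:

```r
p <- setup_walker(walker_params(n_steps = 2000, seed = 11))
noise_sweep(p, mode = "motor")
#>    mode sigma mean_cost_rate sd_step_cost normalized_mean normalized_sd n_falls
#> 1 motor 0.000        0.01105    0.0000000           1.000       0.00000       0
#> 2 motor 0.005        0.01107    0.0008637           1.002       0.05209       0
#> 3 motor 0.010        0.01113    0.0016862           1.007       0.10169       0
#> 4 motor 0.020        0.01130    0.0035866           1.023       0.21631       0
#> 5 motor 0.040        0.01212    0.0076222           1.096       0.45969       0
```

At the largest noise level the walker pays ~10% more than noise-free
walking. Finally, the variance of the N-stride mean cost falls like 1/N,
which is why a multi-stride average is the natural gold standard:

```r
ex <- variance_scaling_experiment(synthetic_gait_config(),
                                  torque_cost_model(),
                                  n_resamples = 500, seed = 3)
ex$table
#>    N  variance
#> 1  1 31514.950
#> 2  2 14727.094
#> 3  5  6403.074
#> 4 10  3155.118
#> 5 20  1577.747
round(ex$loglog_slope, 3)
#> -0.99
```

A thin command-line front end over the same functions lives at
`inst/cli/stridecost.R` (subcommands `synth`, `segment`, `compare`,
`pendulum-sweep`, `varscale`).

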