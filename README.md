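# qslum

Kinetic modelling of quorum-sensing (QS) luminescence dynamics in batch
cultures of luminous bacteria, for microbial physiologists and systems
biologists who want to analyze OD + luminescence time series with a minimal
mechanistic model rather than purely descriptive curves.

A batch culture of luminous bacteria shows a characteristic light signature:
slow dimming while luciferase brought with the inoculum decays, sharp
ignition once the secreted autoinducer crosses the quorum threshold, a single
peak, then a collapse far too fast to be luciferase inactivation. `qslum`
implements a six-variable model that reproduces this signature from four
coupled blocks — ecology, energy, quorum switch, luminescence:

    dS/dt  = -eps0 * N * (fE + k0*fg)          substrate (flask)
    dN/dt  =  fg * N                           biomass
    eps1 * da/dt = fE - k0*fg - kd*a/(eps2+a)  intracellular ATP (fast)
    dA/dt  =  CA * N                           autoinducer
    eps3 * dR/dt = CR + VR*sat(a,a0)*D/(KR+D) - k3*R      LuxR
    eps4 * dL/dt = sat(a,KL)*D/(KR+D) - kdL*L             luciferase
    I      =  VL * L * sat(a,KL)               observed luminescence

with `sat(x,K) = x/(K+x)`, growth `fg = Vg*sat(S,Kg)*sat(a,Ka)`, ATP
production `fE = Ve*sat(S,Ke)*act(a)*(1 - a/a0)+` (adenylate-pool limited),
and the transcription-activating dimer `D = (R*A)^2/gamma` at quasi-steady
state. The package provides:

* stationary-state and regime analysis of the fast ATP equation
  (`stationary_states()`, `regime_scan()`, `energy_demo()`);
* the quorum switch: explicit stationary curve, fold points, bistability and
  hysteresis (`stationary_autoinducer()`, `fold_points()`,
  `hysteresis_loop()`);
* stiff integration of the full model with trajectory diagnostics
  (`simulate_batch()`, `qs_onset_time()`, `lum_peak()`, `post_peak_decay()`,
  `atp_tracking_error()`);
* rich/poor-medium scenario presets and a synthetic-data generator with a
  calibrated observation-noise model (`make_scenario()`, `generate_clean()`,
  `add_noise()`);
* a two-stage derivative-free fitting pipeline — ecology against OD, then
  quorum/luminescence against log-luminescence with stage-1 frozen — built on
  an in-package Nelder–Mead simplex with restarts, parameter profiling and
  multistart (`qs_fit()`, `fit_stage1()`, `fit_stage2()`, `nelder_mead()`,
  `multistart_fit()`), plus a parameter-recovery harness
  (`recovery_experiment()`).

See the vignette (`vignettes/quorum-sensing-batch-model.Rmd`) for the model's
assumptions, parameter meanings and numerical choices.

## Worked example

Simulate the rich-medium preset with the default (common fitted) parameters,
then refit the quorum/luminescence block from data with 5% multiplicative
luminescence noise, starting at half the true values:

```r
library(qslum)

scn  <- make_scenario("rich")
traj <- simulate_batch(scenario = scn)
round(c(onset = qs_onset_time(traj, rel_threshold = 0.1),
        peak_h = lum_peak(traj)$time, peak_I = lum_peak(traj)$intensity,
        decay = post_peak_decay(traj)), 3)
#>   onset  peak_h  peak_I   decay
#>   9.500  13.000 520.737  18.213

obs <- add_noise(generate_clean(scn), noise_config(lum_cv = 0.05, seed = 42))
fit <- qs_fit(obs, scn,
              stage2_start = c(VR = 1.5, CA = 0.14, VL = 600,
                               kdL = 0.5, L0 = 0.2) * 0.5)
summary(fit)
#> Two-stage quorum-sensing model fit — rich scenario, 33 observations
#>
#> Coefficients:
#>         Vg         Kg         S0         N0         VR         CA         VL
#>   2.180000   3.990000  10.000000   0.000030   0.543969   0.170601 607.039000
#>        kdL         L0
#>   0.509610   0.204475
#>
#> Stage 1: loss 9.113e-17 (1 evals) | Stage 2: loss 0.01743 (5840 evals)
#> RMSE: OD 2.343e-05 | log10 luminescence 0.02298
#> Fitted QS onset: 9.5 h | luminescence peak: 13.0 h (I = 518.2)
```

Reading the output: QS ignites at 9.5 h and luminescence peaks at 13 h with a
post-peak decay of 18.2/h — 36x faster than the luciferase inactivation rate
(`kdL = 0.5`/h), the model's signature that the late collapse is energetic,
not proteolytic. Under 5% noise the per-medium luminescence parameters come
back close to truth (`VL` 607 vs 600, `kdL` 0.51 vs 0.50, `L0` 0.204 vs 0.2);
the induced-synthesis rate `VR` is poorly determined from noisy data because
it trades off against the autoinducer production rate `CA` along a shallow
valley of the goal (noise-free it is recovered to ~2%). Stage 1 used a single
evaluation because its starting values were already the generating ones.

The quorum switch in isolation:

```r
fold_points(reduced_qs_params(alpha = 0.1, beta = 1, sigma = 1))
#> Bistable quorum switch: folds at R = 0.238197 / 0.461803;
#>   up-switch A = 1.68116, down-switch A = 1.63043
```

A command-line interface wrapping the same functions ships in
`inst/scripts/qslum` (subcommands `simulate`, `analyze-energy`, `analyze-qs`,
`synth`, `fit`, `recover`).

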