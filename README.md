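# purkinjetimer

Kinetic simulation of time-interval learning inside a single Purkinje-cell
dendrite during delay eyeblink conditioning.

In delay conditioning a neutral conditioned stimulus (CS, the
parallel-fiber input) is followed at a fixed inter-stimulus interval (ISI)
by the unconditioned stimulus (US, the climbing-fiber input). Experiments
with direct afferent stimulation suggest Purkinje cells store the learned
interval intracellularly rather than in synaptic weights. This package
implements a biophysical model of that mechanism for people studying
cerebellar timing, classical-conditioning biophysics, or second-messenger
kinetics: a calcium store acts as a clock started by the CS, adenylyl
cyclase detects the coincidence of the calcium signal with the US-evoked
Gs protein, the cAMP–PKA pathway feeds back positively on calcium release,
and a calcium-gated RGS protein — the timed output — learns to activate
just before the expected US.

## The model

Eleven coupled species in a well-mixed microdomain (concentrations in µM,
time in s), integrated with fixed-step backward Euler at 25 µs:

* calcium store (Somogyi–Stucki): `dx/dt = k1*y − k2*x − α f(y) x`,
  `dy/dt = k2*x − k1*y + α f(y) x + γ − β y`, with the CICR fraction
  `f(y) = y^n / (y^n + h^n)`; a CS loads the pool (`x = 25`) and opens a
  2 s window in which the synaptic calcium read-out is
  `[Ca²⁺] = (1 + 10[PKA]) y` (basal `B_Ca` otherwise);
* CS-driven inhibitory G protein `Gi = a e^{bt}` (1.2 s growth, cleared at
  2 s) and US-driven `[Gs] = 5 K_g³/(K_g³ + [RGS]³)` for 200 ms;
* adenylyl cyclase `d[AC]/dt = r1[ACi] − r2[AC]` with the synergistic
  activation `r1 = r1_bl + r_cag [Gs] · Ca³/(K_ca³+Ca³) · K_Gi/(K_Gi+Gi)`
  and `r2 = r2_bl + r_ca·Ca` — calcium alone never activates AC;
* cAMP/PKA/PDE kinetics with conserved totals (`inactive = total −
  active`);
* the RGS output: `d[RGS]/dt = (r5 + α)(1 − [RGS]) − r6[RGS]` gated by the
  switch `α = 1{z > 0.1}`, where `dz/dt = r3(1 − z) − r4 z` and
  `r3 = r3_bl · Ca²/(K_ca + Ca)`.

The model's "response time" is the first post-CS crossing of the `z`
switch. Training moves it from about one second *after* the US on the
first pairing to just *before* the US, at which point RGS suppression of
Gs freezes further learning.

The authoritative parameter table of the original study was not available,
so the shipped defaults are **re-calibrated** with the package's own
constraint-guided calibration module and are one working set among many —
see `?model_parameters` and the vignette.

## A worked example

```r
library(purkinjetimer)
params <- default_parameters()
config <- integrator_config(dt = 1e-4, record_stride = 10)

res <- run_training(training_protocol(11, isi_ms = 150), params, config)
round(res$rgs_activation_time, 3)
#>  [1] 1.112 0.329 0.242 0.208 0.189 0.176 0.168 0.161 0.156 0.152 0.148
res$anticipated
#>  [1] FALSE FALSE FALSE FALSE FALSE FALSE FALSE FALSE FALSE FALSE  TRUE

calcium_amplification(run_training(training_protocol(2, 150), params, config))
#> [1] 102.3038
```

Reading: on the first pairing the RGS switch engages 1.11 s after the CS —
about 0.96 s *after* the climbing-fiber input at 0.15 s — and over eleven
pairings the latency walks in until it precedes the US (0.148 s < 0.15 s):
the interval is learned. A second pairing releases ~102% more calcium than
the first, the PKA-amplification signature. An interval sweep
(`isi_sweep(c(150, 300, 500, 750, 1000), ...)`) learns every interval
within 70 pairings, with the number of pairings growing with the ISI
(11, 11, 26, 47, 48).

A command-line front end wrapping these functions is installed at
`inst/cli/purkinjetimer.R` (subcommands `simulate`, `train`, `sweep`,
`calibrate`).

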