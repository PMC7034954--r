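---
title: "A kinetic model of interval timing in a Purkinje-cell dendrite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of interval timing in a Purkinje-cell dendrite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 5)
library(purkinjetimer)
```

## The problem

In delay eyeblink conditioning a neutral conditioned stimulus (CS, carried
to the Purkinje cell by parallel fibers) is followed after a fixed
inter-stimulus interval (ISI) by an unconditioned stimulus (US, the
climbing-fiber input). After repeated pairings the Purkinje cell produces a
response timed just before the expected US. Experiments with direct
afferent stimulation indicate that this timing is stored inside the
Purkinje cell rather than in conventional synaptic weights: interrupting
or re-scaling the parallel-fiber drive does not change the expressed
interval, and blocking the metabotropic receptor mGluR7 abolishes it.

This package implements a biophysical model of that intracellular
mechanism in a single well-mixed dendritic microdomain. It contains five
interacting elements:

* **a decoupling mechanism** — the CS onset saturates IP3 production and
  loads a fixed amount of calcium into a local store; subsequent drive is
  irrelevant, so only the onset time enters the dynamics;
* **a calcium clock** — the store releases calcium along a stereotyped
  transient (a two-variable store/cytosol oscillator with
  calcium-induced calcium release), so elapsed time since the CS is
  encoded in the calcium trajectory;
* **a coincidence detector** — adenylyl cyclase (AC), activated
  synergistically by the calcium signal and by the stimulatory G protein
  (Gs) that the US liberates, and inhibited by the CS-driven Gi transient;
* **a positive feedback** — AC produces cAMP which activates PKA; PKA
  sensitizes the IP3 receptor, so the *read-out* calcium is amplified by
  `1 + 10*PKA` on later trials, advancing every downstream threshold
  crossing;
* **a negative feedback** — a calcium-gated RGS protein whose activation
  time is the model's timed output; once it activates before the US it
  suppresses the Gs input and thereby freezes further learning.

Training moves the RGS activation time from about one second after the US
(first pairing) to just before the US (trained state): the model has
learned the interval.

## Equations

All concentrations are in µM and time in seconds. The calcium store
follows the two-variable oscillator

$$\frac{dx}{dt} = k_1 y - k_2 x - \alpha f(y)\,x, \qquad
  \frac{dy}{dt} = k_2 x - k_1 y + \alpha f(y)\,x + \gamma - \beta y,$$

with the calcium-induced-release fraction
$f(y) = y^n/(y^n + h^n)$. At a CS the pool is loaded ($x = 25$) and for
the following 2 s the synaptic calcium read-out is
$[\mathrm{Ca}^{2+}] = (1 + 10\,[\mathrm{PKA}])\,y$; outside that window it
is the basal level $B_{Ca}$.

The CS also raises the inhibitory G protein, $G_i = a e^{b t}$ for 1.2 s
(held, then cleared at 2 s), while the US generates the stimulatory
G protein for 200 ms, gated by active RGS:
$[G_s] = 5 K_g^3 / (K_g^3 + [\mathrm{RGS}]^3)$.

Active adenylyl cyclase follows
$d[\mathrm{AC}]/dt = r_1 [\mathrm{AC}_i] - r_2 [\mathrm{AC}]$ with the
synergistic activation rate

$$r_1 = r_{1bl} + r_{cag}\,[G_s]\,
       \frac{[\mathrm{Ca}^{2+}]^3}{K_{ca}^3 + [\mathrm{Ca}^{2+}]^3}\,
       \frac{K_{Gi}}{K_{Gi} + [G_i]}, \qquad
  r_2 = r_{2bl} + r_{ca} [\mathrm{Ca}^{2+}].$$

Without Gs, $r_1$ stays at baseline: calcium alone does not activate AC —
that is the coincidence detector, and it is order-sensitive because the
Gs window is short and calcium takes time to rise.

The cAMP–PKA–PDE chain is

$$\frac{d[\mathrm{cAMP}]}{dt} = k_8 [\mathrm{AC}]
    - \frac{k_{10} [\mathrm{PDE}][\mathrm{cAMP}]}{k_m + [\mathrm{cAMP}]},
  \qquad
  \frac{d[\mathrm{PKA}]}{dt} = k_{a7} [\mathrm{PKA}_i][\mathrm{cAMP}]
    - k_7 [\mathrm{PKA}],$$
$$\frac{d[\mathrm{PDE}]}{dt} = k_{13}
    + \frac{k_{14} [\mathrm{PKA}][\mathrm{PDE}_i]}{k_{m2} + [\mathrm{PDE}_i]}
    - k_{15} [\mathrm{PDE}],$$

with every inactive pool closed by conservation
(`inactive = total - active`); the totals come from the initial
concentrations. The RGS output is a thresholded integrator of the calcium
signal:

$$\frac{d[\mathrm{RGS}]}{dt} = (r_5 + \alpha)(1 - [\mathrm{RGS}])
      - r_6 [\mathrm{RGS}], \qquad
  \alpha = \mathbf{1}\{z > 0.1\}, \qquad
  \frac{dz}{dt} = r_3 (1 - z) - r_4 z,$$

with $r_3 = r_{3bl}\,[\mathrm{Ca}^{2+}]^2 / (K_{ca} + [\mathrm{Ca}^{2+}])$
implemented exactly in this printed form (quadratic numerator over a
linear denominator). The model's "activation time" is the first
post-CS crossing of the $z$ switch — the quantity the negative feedback
itself uses. An alternative criterion (RGS reaching a fraction of its
trial maximum) is available for figure-style read-outs.

## How learning works, mechanically

On the first pairing the naive calcium transient alone cannot drive the
gating variable $z$ across its threshold (its maximum sits safely below
0.1), but the US-evoked cAMP pulse raises PKA through the trial, the
read-out gain `1 + 10 PKA` lifts $r_3$, and $z$ crosses about one second
*after* the US. Because cAMP synthesis is hydrolysis-limited and the
calcium signal itself starts slowly, the first trial's PKA is
back-loaded: it is still small while most of the trial's calcium is
released, so the first trial's release is nearly unamplified, while the
second trial carries the accumulated PKA from its very start — which is
what produces the roughly-100% increase in released calcium on the second
pairing.

Across pairings PKA accumulates, each trial's activation time moves
earlier along the calcium transient, and two brakes shape the approach:
the PKA-activated phosphodiesterase raises the hydrolysis capacity seen by
later cAMP pulses, and — decisively — once the activation time enters the
200 ms Gs window, the rising RGS suppresses Gs in proportion to how early
it activates. Learning therefore converges onto an activation time just
before the US instead of collapsing to zero, at every interval.

Longer intervals are learned more slowly for two reasons: the Gi
transient grows exponentially after the CS, so a later US finds a more
strongly inhibited cyclase, and the calcium transient has decayed, so the
cubic calcium term of $r_1$ is far from saturation. Both factors shrink
the per-pairing PKA increment with the ISI, which reproduces the
increasing pairings-to-learn curve. Intervals shorter than the
calcium-signal onset lag are not learnable at all: at the US the calcium
is still near basal, the synergy never engages, and no amount of pairing
accumulates PKA.

## Numerical scheme

The production integrator is fixed-step backward Euler at 25 µs, matching
the original simulations; there is no adaptive step-size control. Each
step solves the implicit update with damped fixed-point iteration
(tolerance $10^{-10}$ relative), falling back to a Newton iteration with
a finite-difference Jacobian on the rare stalls. Discontinuous inputs —
the stimulus windows and the $z$ switch — are evaluated at the step's end
time; if the switch flips inside the iteration the step is accepted with
the flipped branch (no hysteresis). Stimulus onsets must fall on the step
grid, which the 25 µs step guarantees for millisecond-resolution
protocols. A classical fourth-order Runge-Kutta method over the same
right-hand side serves as a cross-validation oracle: at 25 µs the implicit
scheme tracks a 1 µs RK4 run within 0.5% on a full pairing, and halving
the step changes trajectories by well under 1%, which is why coarser
steps (100–200 µs) are used for long training sweeps and calibration.

The model is fully deterministic: identical parameters, protocol and
integrator configuration reproduce traces bit-for-bit.

## Trials, carry-over and initial conditions

A trial applies the CS at its onset (pool set to $x = 25$, cytosolic
calcium to its resting value $\gamma/\beta$, read-out window and Gi
transient started) and the US one ISI later (Gs window). Trials last
until all stimulus windows have closed (default: US onset + 2.5 s). The
slow species (AC, cAMP, PKA, PDE, RGS, $z$) persist across trials and
relax without stimulation during the inter-trial interval (default 10 s);
the fast stimulus-driven quantities (pool and cytosolic calcium, G-protein
inputs, stimulus timers) are re-initialized at each CS. Before the first
trial the pathway species sit at their configured initial concentrations,
active PKA and RGS at zero, and the oscillator at its unstimulated fixed
point.

The printed initial concentrations contain one duplicated label, so two
readings are exposed as presets of `model_parameters()`:
`"pde-inactive-5"` (default; 0.1 µM inactive AC and 5 µM inactive PDE)
and `"ac-active-5"` (0.1 µM active AC, 5 µM inactive AC). The shipped
calibration uses the default preset; the alternative is provided for
sensitivity analysis rather than silently chosen.

The CS descriptors `cs_duration` and `cs_strength` are carried through the
protocol objects but never read by the dynamics. That is deliberate: the
decoupling property — identical traces under interrupted or re-scaled
parallel-fiber drive — holds by construction and is asserted by tests.

## Parameters and calibration

The authoritative parameter table of the original study is not available
to this package, so the shipped defaults are **re-calibrated and
non-authoritative**: one working set, derived with the package's own
calibration module, that reproduces the documented behaviors —

* resting stationarity (no drift, no spontaneous RGS activation);
* no timed response of the naive model to a CS alone;
* first-pairing RGS activation about one second after the US at a
  150 ms ISI;
* roughly 100% more calcium released on the second pairing;
* anticipation at a 150 ms ISI after about 11 pairings;
* every ISI between 150 and 1000 ms learned within 70 pairings, with
  pairings-to-learn non-decreasing in the ISI.

`calibrate_parameters()` performs seeded Latin-hypercube sampling over
log-scaled bounds followed by local coordinate refinement of
`score_parameters()`, which returns a weighted sum of banded constraint
violations (zero exactly when every constraint is met). The search is
deterministic given the seed, idempotent at feasible points, and reports
per-constraint violations. Simulation failures score a large finite
penalty rather than aborting the search.

Parameters that the model fixes on principle rather than by calibration:
the PKA read-out gain (10), the pool load at a CS (25 µM), the 2 s
read-out window, the 1.2 s Gi growth window and its 2 s cutoff, the
200 ms Gs window, the Gs scale (5 µM), and the switch threshold
($z > 0.1$, strict).

## What the simulations do and do not show

The protocol engine generates exactly the study conditions: deterministic
single-compartment kinetics, stimulus onsets as instantaneous events, and
evenly spaced training trials. Real dendrites add spatial calcium
diffusion, stochastic channel gating, receptor desensitization, spiking,
and trial-to-trial variability — none of which is modeled. Passing tests
therefore demonstrate that the *mechanism* (clock + coincidence detector
+ feedback loops) self-organizes to the trained interval under the
modeled kinetics, not that the specific rate constants describe a real
Purkinje cell. Membrane potential and the firing pause itself are out of
scope; anticipatory RGS activation stands in for the conditioned
response.

## A worked example

```{r example, eval = FALSE}
params <- default_parameters()
config <- integrator_config()      # backward Euler, 25 us steps

# one CS-US pairing at a 150 ms ISI
trial <- conditioning_trial(cs_onset = 0.1, us_onset = 0.25)
first <- run_trial(initial_state(params), trial, params, config)
plot(first$trace)

# eleven pairings: the activation latency walks in toward the US
# (1.11 s on the first pairing, 0.148 s — anticipating — on the eleventh)
training <- run_training(training_protocol(11, isi_ms = 150),
                         params, config)
training[, c("trial", "rgs_activation_time", "anticipated")]

# learning curve across intervals (coarser step for the long sweep)
sweep <- isi_sweep(c(150, 300, 500, 750, 1000), params,
                   integrator_config(dt = 1e-4, record_stride = 10),
                   max_pairings = 70)
sweep
```

The problem sizes used throughout the package's tests — two to eleven
pairings at 25 µs steps, and 70-pairing sweeps at 100–200 µs — were chosen
so each check isolates one documented behavior at the smallest protocol
that expresses it.

## Known limitations

* The calibrated defaults are one point in a large feasible set; other
  parameter vectors reproduce the same behaviors. Conclusions should rest
  on the mechanism, not on individual rate constants.
* The activation-time read-out is resolved at the trace recording stride
  (1 ms by default).
* The naive model's CS-evoked gating variable deliberately approaches the
  switch threshold without crossing it (that near-miss is what lets a
  single US-paired trial activate late); behavior near that margin is
  sensitive to large parameter perturbations, and `validate_parameters()`
  cannot check it statically — `score_parameters()` can.
* The order dependence of the coincidence detector holds in the
  conditioning direction (a US delivered before the CS activates AC
  strictly less than one delivered after), but a US delivered
  *simultaneously* with the CS is not strongly penalized in this
  parametrization: the CS-locked Gi transient, which grows steeply after
  CS onset, partially offsets the weak early calcium at very short
  offsets.
* Multi-synapse stochastic learning of several intervals, long-term
  consolidation, and the olivary feedback loop are outside the model's
  scope.
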