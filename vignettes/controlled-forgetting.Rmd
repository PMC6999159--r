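---
title: "Controlled forgetting in spiking networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled forgetting in spiking networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfnet)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, the numerical choices, and the
places where the design was genuinely open.

## The model

A single competitive layer of `N` leaky integrate-and-fire (LIF) neurons
receives rate-coded input. A sample is a non-negative vector `x`; each
channel fires as an independent Poisson process with rate proportional to
its intensity, and the rate vector is L2-normalized to one spike per time
unit in total magnitude. All timing in the package is relative to that
unit; there is no wall-clock calibration. Membrane potentials decay as
`v' = -v/tau_mem` (resting and reset potentials fixed at 0 as the
reference voltage, no refractory period) and each input spike on channel
`i` adds the synaptic weight `w_ij` instantaneously, giving an exponential
kernel response. A neuron fires when `v >= v_th` (inclusive) and resets;
lateral inhibition then resets the rivals (hard winner-take-all by
default), so one neuron claims each recognition event.

Simulation is purely event-driven. Because neurons can only cross
threshold when an input spike arrives, the simulator draws the next input
spike time from the pooled exponential law, advances every state variable
by the closed-form decay, and processes the spike. The one exception is
the dopaminergic unit, which fires in the *absence* of input: its
closed-form time-to-fire is compared against the next input spike and the
earlier event is processed first (ties, a measure-zero event in continuous
time, go to the input).

### Plasticity

Learning is a one-sided STDP rule evaluated only at post-synaptic firing
events. Each input channel carries a trace that decays with
`tau_pre = 200` and is incremented by exactly 1 at each spike; at
stationarity its expectation is `lambda_i * tau_pre`, which forces the
unit increment — any other increment would break the scaling between the
trace and the rate it estimates. The update

\[ \Delta w = \alpha\,(\mathrm{pre}/\tau_{pre} - w) \]

ties the anti-Hebbian offset to the current weight (an Oja-style
stabilization), so the fixed point is the input-rate direction itself and
no adaptive threshold is needed for stability. The classical static-offset
variant `alpha * (pre - offset)` is implemented as the instability
reference: driven at its own fixed point it migrates toward the axes and
binarizes against the clip bounds (`stdp_drive_experiment()` reproduces
both behaviours). Weights are clipped to `[0, w_cap]` with `w_cap = 0.2`
*before* L2-normalization on every update; clipping first keeps stochastic
trace outliers from distorting the normalization during one-shot learning.
We apply the cap on every update, not only during boosted updates — the
stability argument for it is general, and a cap that appears only under
dopamine would make the rule discontinuous in `alpha`.

### The dopaminergic unit

The novelty detector is a self-firing neuron: resting potential
`v_rest = 2` above its threshold `v_th = 1`, rise constant
`tau_d = 200/ln 2`, reset to 0, inhibited subtractively by every
output-layer spike. From reset it fires after exactly
`tau_d * ln((2-0)/(2-1)) = 200` time units — one recognition window — so
it fires precisely when a sample has gone unrecognized for a full window.
On firing it sets every neuron's learning rate to `alpha = 1` (from the
base 0.01) and delivers excitatory increments `gain * d_j` through the
dopaminergic weights `d_j`, with `gain = kappa * v_th / max(d)`; at the
default `kappa = 1` the most-targeted neuron is guaranteed to reach
threshold. The winner performs one boosted update — adopting the current
trace direction in a single shot — and the resulting lateral inhibition
resets every other neuron's boost, so exactly one weight vector changes
per novelty event. Dopaminergic weights are depressed multiplicatively
(`d_j <- d_j (1 - eta)`, default `eta = 0.1`) each time neuron `j` fires
and the fan-out is L2-renormalized; the renormalization *is* the gradual
potentiation of the others, since only the relative order of the `d_j`
matters. Frequently used neurons are therefore protected and the
least-used neuron is sacrificed to novel data — forgetting happens, but it
is aimed at the least valuable representation.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau_mem` | 15 | time units | membrane integration horizon; sets the mean/variance trade-off of the potential |
| `v_th` | 13.5 | voltage | static threshold; just below the matched steady-state mean `tau_mem * (w.lambda)` |
| `tau_pre` | 200 | time units | trace horizon; matches the recognition window so one-shot adoption sees the whole sample |
| `recognize_time` | 200 | time units | window without recognition before escalation / dopamine |
| `recognize_spikes` | 5 | spikes | output spikes that count as recognition |
| `alpha_base`, `alpha_boost` | 0.01, 1.0 | — | gradual refinement vs one-shot adoption |
| `w_cap` | 0.2 | weight | per-weight clip bound before normalization |
| `tau_d` | 200/ln 2 | time units | dopaminergic rise; fires 200 units after reset |
| `dopamine_inhibit` | 2.0 | voltage | inhibition per output spike; one spike postpones the next dopamine fire by a full rise period |
| `eta` | 0.1 | — | dopaminergic depression fraction per post-synaptic fire |
| `kappa` | 1.0 | — | stimulation gain; 1 makes targeting deterministic |
| `escalation_factor`, `escalation_max` | 1.5, 10 | — | inference-time rate escalation policy |

The defaults are the operating point for 784-channel handwritten-digit
data. The threshold logic transfers to other data through the moment
formulas: for unit-norm weights and rates the steady-state mean potential
is `tau_mem * cos(w, lambda)`, so `v_th` should sit at roughly 0.9 of the
within-cluster value. For the 64-channel synthetic study below that gives
`v_th = 12.5`, which is what `lifelong_benchmark()` uses.

## Theory module

`mean_potential()` and `var_potential()` implement the shot-noise moments
of the pre-firing potential; `monte_carlo_potential()` is an independent
oracle that places Poisson spike counts uniformly in the window and sums
kernel contributions directly. One printed-form ambiguity is resolved
deliberately: the ratio `Var/E` of these moments is independent of
`tau_mem`, so the advertised `1/tau` scaling can only refer to the squared
coefficient of variation `Var/E^2`; `cv_squared()` implements that
reading, and the package documents rather than reproduces the
dimensionally inconsistent form. Similarly, a literal rise constant of
`200 ln 2` for the dopaminergic unit would make it fire after ~96 time
units, contradicting the stated 200-unit objective that every other
constant is built around; the package uses `200/ln 2`, which satisfies it
exactly.

## The synthetic data generator

`generate_synthetic()` emulates the geometry that makes rate-coded image
data learnable by an angular classifier, at desk scale (64 channels, 4
classes × 3 clusters, 60 samples per class by default): non-negative
sparse samples, tight within-cluster angular spread
(`noise_sd = 0.02`, realized within-cluster dot ≈ 0.98), large
between-class angular separation, and magnitude-irrelevant class identity.
Two hard constraints fixed the default geometry:

* **The weight cap sets a minimum support.** A unit-norm weight vector
  with entries capped near 0.2 must spread over at least
  `1/w_cap^2 = 25` channels; narrower cluster centers cannot be
  represented and the clip/renormalize cycle flattens them. Centers
  therefore carry ~29 active channels (sparsity 0.55).
* **Catastrophic reuse must be possible.** The baselines can only exhibit
  catastrophic forgetting if a trained representation of an old class is
  angularly *closer* to a new class than an unused random weight vector —
  the geometry real digit data has, where all classes share central ink
  mass. Centers therefore share a block of high-intensity "core" channels
  (between-class dot ≈ 0.58) while dense random weight vectors sit at
  ≈ 0.50 from every class.

Each class additionally owns a few private channels and each cluster a few
cluster-specific ones; samples are `center + N(0, noise_sd)` clipped at
zero and renormalized. Realized within-cluster and between-class dot
products are measured on the generated samples and centers are redrawn
(bounded retries) if the configured targets
(`intra_dot_min = 0.9`, `inter_dot_max = 0.65`) are violated.

What the generator does **not** emulate: the heavy-tailed cluster-size
distribution of real handwriting, within-class style continua (clusters
here are isotropic blobs), correlated pixel noise, and the ~10× higher
dimensionality. Passing the benchmark therefore demonstrates the
*mechanism* — targeted one-shot reassignment protecting earlier classes —
not digit-level accuracy figures, which require the real dataset (the IDX
reader and the same protocol functions support that run unchanged).

## Protocols

In the disjoint scenario classes are presented strictly sequentially and
never revisited; after each task the network is frozen, every neuron is
assigned the class for which it spiked most during inference on the
training samples of all classes seen so far, and accuracy is evaluated on
the held-out samples of those classes (never future ones). No linear
readout is ever fitted. Label assignment uses all seen classes rather than
only the current task: inference on the training set is cheap, and
restricting it would leak task boundaries into evaluation, which the
protocol is specifically designed to avoid. During training of the
dopaminergic network input rates are never escalated (the dopaminergic
unit handles poor matches); during inference — and during training of the
non-dopaminergic baselines, which have no other recourse — rates are
multiplied by 1.5 after every unanswered 200-unit window, up to 10 times,
after which classification falls back to accumulated spike counts and
then to membrane potentials, flagged in the result.

The benchmark (`lifelong_benchmark()`) runs 5 seeds × {dopaminergic,
no-dopamine, no-dopamine + adaptive-threshold homeostasis, frozen random
weights} on the default synthetic study (N = 32, `v_th = 12.5`, 3 epochs
per task, 80/20 split). Three epochs per task is the smallest setting at
which the homeostasis baseline's characteristic failure — corruption
spread over previously used neurons — compounds enough to be measured,
while the dopaminergic network only refines its adopted clusters. The
homeostasis constants (`theta_plus = 0.05`, `tau_theta = 1e5`) are
baseline-only knobs; the dopaminergic network uses static thresholds
precisely because its targeted stimulation is itself a deliberate form of
homeostasis.

## Numerical and tie-breaking choices

* **Dopamine-event winner.** With `kappa = 1` the stimulation increments
  are of order `v_th`, so several neurons may cross threshold in the same
  dopamine event. The winner is the neuron that would cross *first* under
  a continuously ramped stimulation, i.e. the one minimizing
  `(v_th_eff - v) / d_j` — exactly the semantics of a signal that persists
  until the first fire. A naive lowest-index rule here would defeat the
  targeting whenever residual potentials are nonzero. For input-spike
  events, where simultaneous crossings are a knife-edge, the lowest index
  wins.
* **Ties elsewhere.** Label assignment ties go to the lowest class index;
  classification ties to the lowest neuron index. Both are deterministic
  and documented.
* **Silent inputs.** An all-zero rate vector cannot be normalized
  (`normalize_rates()` refuses it); if a silent presentation is forced on
  the simulator, dopamine-stimulated fires skip the weight update rather
  than letting `alpha = 1` erase the weights against an all-zero trace.
* **Degenerate weights.** If clipping ever produces an all-zero vector
  the update aborts with an error rather than silently renormalizing.
* **Between-sample reset.** Membrane potentials, pre-traces and the
  dopaminergic potential reset between samples; synaptic weights,
  dopaminergic weights, learning-rate states (back to base) and
  homeostasis offsets persist.
* **Reference integrator.** `present_sample_stepped()` re-implements the
  presentation on a dense grid (`dt = 0.005`) with exact per-step decay
  factors; the event-driven loop is validated against it for identical
  spike sets, event times within the grid resolution, and final potentials
  within 1e-2. The dopaminergic crossing is additionally checked against a
  forward-Euler integration, a genuinely different discretization.

## Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen
for statistical resolution, not fidelity to the full study: 10^4–10^5
Monte-Carlo draws for distributional checks (4-standard-error bands),
500-update STDP convergence runs, a 5-neuron/8-channel injected-schedule
equivalence run, and the 5-seed benchmark above (~3,400 sample
presentations per seed). The full-scale digit experiment (400–6,400
neurons, 10 classes) is supported by the same code paths via the IDX
reader but requires the external dataset and hours of CPU.

## Known limitations

* Hard winner-take-all is the default inhibition; the subtractive mode is
  retained for sensitivity analysis but the protocols assume a dominant
  winner.
* No spike-transmission delays, conductance synapses or refractory
  dynamics; all are out of scope of the model.
* The dopaminergic inhibition magnitude (2.0 per output spike) and the
  depression fraction `eta = 0.1` are design constants with documented
  rationale (one spike postpones the next dopamine fire by a full rise
  period; only relative order of dopaminergic weights matters), not fitted
  quantities.
* Accuracy figures on the synthetic benchmark are near ceiling by design;
  they measure the presence/absence of catastrophic forgetting, not
  classifier quality.
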