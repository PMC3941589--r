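---
title: "A sparseness-driven differential-Hebbian plasticity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sparseness-driven differential-Hebbian plasticity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsehebb)
```

## The model

Cortical excitatory synapses have heavy-tailed, approximately lognormal
strength distributions: most synapses are weak, a few are very strong. This
package simulates the hypothesis that such *sparseness* is not a byproduct
but the objective of long-term plasticity: each synapse performs stochastic
gradient ascent on the skewness (or kurtosis) of its local membrane
potential, which serves as a proxy for the strength distribution of all
synapses converging on the neuron.

Over a short window $\delta$ the local potential is approximated as a
drifting Wiener process,
$u(t_0+\delta) \approx u(t_0) + \dot u(t_0)\,\delta + \sigma X_\delta$,
whose time-averaged raw moments of the mean-free potential
$\hat u = u - \bar u$ have closed forms; `wiener_moment()` implements the
second moment

$$\langle\hat u^2\rangle_\delta = \hat u^2 + \tfrac12(\sigma^2 +
2\hat u\dot u)\delta + \tfrac13\dot u^2\delta^2$$

and the third moment

$$\langle\hat u^3\rangle_\delta = \hat u^3 + \tfrac32\hat u(\hat u\dot u +
\sigma^2)\delta + (\hat u\dot u^2 + \dot u\sigma^2)\delta^2 +
\tfrac14\dot u^3\delta^3,$$

which is derived here from first principles as the time average of Gaussian
raw moments with mean $\hat u + \dot u t$ and variance $\sigma^2 t$ (the
printed source for this particular expression is not machine-readable, so
`monte_carlo_moments()` provides an independent simulation oracle and the
test suite requires agreement within three standard errors before the
closed form is used anywhere else).

Differentiating the instantaneous "sample" skewness
$S^*_u = \langle\hat u^3\rangle_\delta / \langle\hat u^2\rangle_\delta^{3/2}$
with respect to $\dot u$, the order-$\delta^0$ terms are constant and the
order-$\delta$ terms cancel exactly (a property the tests verify by the
log–log slope of the numerical derivative), leaving the regularized gradient

$$\frac{\partial S^*_u}{\partial\dot u} \approx \tfrac14\,
(\dot u\hat u - 2\sigma^2)\,\frac{|\hat u|^3}{\hat u^6 + \gamma^6}\,\delta^2 .$$

The $\delta^2$ factor is absorbed into the learning rate. Chaining through
$\partial\dot u/\partial w_R = I_R/C$ gives the per-receptor-type rule

$$\dot w_R = \eta\,\frac{I_R(t)}{C}\,\tfrac14(\dot u\hat u - 2\sigma^2)\,
\frac{|\hat u|^3}{\hat u^6+\gamma^6},$$

a differential-Hebbian rule ($\dot w_R \propto \dot u\, I_R$ when the noise
term is neglected). The kurtosis variant replaces the gradient with
$\tfrac23(\dot u\hat u - 1.5\sigma^2)\hat u^5/(\hat u^8+\gamma^8)$; being an
even-moment measure its depression branch does not flip sign with $\hat u$.
The reference $\bar u$ is a slow exponential average of the local potential
(exact per-step update, time constant $\tau_{\bar u}$) and is what gives the
rule its BCM-style metaplasticity: a history of high activity raises
$\bar u$ and biases subsequent induction toward depression.

### Parameters of the rule

| parameter | meaning | default |
|---|---|---|
| $\eta$ | learning rate | 1.5 s |
| $\gamma$ | gradient regularization | 10 mV |
| $\sigma^2$ | channel-noise intensity | 0.036 mV$^2$/ms |
| $\tau_{\bar u}$ | reference-potential time constant | 30 s |
| $C_{\mathrm{eff}}$ | effective local capacitance | 1.5 pF |

The first four are the phenomenological constants of the rule and are held
fixed across every protocol. $C_{\mathrm{eff}}$ converts current into
voltage slope inside the rule; in a reduced cable there is no uniquely
correct value (the local input capacitance depends on morphology), so it is
the one overall plasticity-magnitude constant of the model. It was set once
so that the standard pairing protocol (7 pairings at 1 Hz) produces changes
of tens of percent, and then frozen.

## The reduced neuron

The electrical substrate is a passive ball-and-stick model: a lumped
spherical soma (20 µm) plus a single unbranched apical cable (800 µm, 60
compartments, 2 µm diameter, $R_i$ = 110 Ω·cm, $R_m$ = 30 kΩ·cm²,
$C_m$ = 1 µF/cm², rest −70 mV), integrated with the unconditionally stable
implicit method at dt = 0.1 ms. Synapses live in two-compartment spines
(neck 1 × 0.1 µm, head 0.6 × 0.3 µm) condensed exactly onto their shaft
node at each step; the rule reads $u$, $\dot u$ and $\bar u$ at the spine
head. AMPA and NMDA conductances are triple exponentials with unit-peak
normalization; the NMDA channel carries the voltage-dependent magnesium
block $(1 + [\mathrm{Mg}]_o/\beta\,e^{-\alpha u})^{-1}$ with
$[\mathrm{Mg}]_o$ = 1 mM, $\alpha$ = 0.062 /mV, $\beta$ = 3.57 mM.

Three design choices in the spike mechanism deserve explanation:

* **The action potential is imposed through a conductance, not an exact
  voltage command.** The somatic AP is a stereotyped waveform (difference of
  exponentials, 85 mV peak, rise 0.3 ms, decay 3.5 ms), but driving it as a
  hard voltage assignment pins the soma to the waveform's resting tail
  between high-frequency spikes, draining the dendrite back to rest every
  cycle. That destroys the depolarization accumulation on which the
  repetition-frequency effects (50 Hz potentiation, the depression-to-
  potentiation crossover) depend. Instead the waveform is enforced through
  a strong conductance toward the command voltage (peak 3000 nS, decaying
  as the squared waveform shape), which dominates during the spike and
  hands the membrane back to its own dynamics in the tail.
* **Numerics of the rule along fast sweeps.** The gradient is sharply
  peaked in $\hat u$ (width $\sim\gamma$), and a bAP rise crosses its
  support within one or two integration steps. Sampling the gradient at
  step endpoints systematically biases the rise/decay balance (and with it
  the whole STDP window), so the engine integrates the gradient along the
  within-step voltage path with midpoint substeps of at most 0.25 mV, and
  evaluates the magnesium unblock at the substep voltage rather than with
  the one-step lag used by the implicit cable solve. With these two
  choices, halving dt changes protocol outcomes by only a few percent.
* **Adaptive spike threshold.** Threshold-triggered firing (used when a
  synapse population drives the cell) raises the threshold by 1 mV per
  spike, decaying with τ = 300 ms. A fixed threshold makes the population
  regime bistable — silent, or firing at the refractory limit until the
  weights collapse — whereas real pyramidal cells self-regulate through
  adaptation currents. The adaptation affects only threshold detection;
  scheduled APs and eliciting current pulses are unchanged.

The eliciting pulse for postsynaptic spikes is 2 nA for 3 ms (interpreted
from a printed value whose unit is physiologically implausible by six
orders of magnitude), and pulses arriving within the 18 ms refractory
period are ineffective. The cable and AP constants above were calibrated
*once*, jointly, against the structure of the published protocol results —
the ~20 ms depression window of the pairing protocol, the
depression-to-potentiation crossover near 30 Hz, and the
potentiation-to-depression switch around 700 µm — and then frozen; no
parameter was revisited afterwards.

## Protocols and the synthetic stimulus generator

All stimuli are generated internally: seeded homogeneous Poisson trains
(`poisson_train()`, with the seed never touching the global RNG stream),
deterministic pairing schedules, 100 Hz × 3 s priming bursts of scheduled
APs, and somatic voltage-clamp commands. Synaptic strength is always
measured as the somatic EPSP peak of a single test pulse delivered from
rest with plasticity frozen and spiking disabled; protocol outcomes are
relative changes of that peak. The runners are:

* `run_stdp_pairing()` / `run_delay_sweep()` — pre/post pairings at a fixed
  delay (7 at 1 Hz by default, synapse at 200 µm with 200 pS AMPA and
  500 pS NMDA).
* `run_frequency_sweep()` — 100 pairings at ±10 ms versus repetition
  frequency for a proximal NMDA-only synapse (150 µm).
* `run_rate_protocol()` — independent pre (10 Hz) and post (conditioning
  rate) Poisson trains for 30 s; $\bar u$ starts at the value implied by a
  10 Hz postsynaptic history (computed from single-event voltage
  integrals), and the priming variant prepends the 100 Hz burst.
* `run_voltage_clamp()` — 100 stimuli at 2 Hz to a distal (700 µm)
  NMDA-only synapse under an ideal somatic clamp, optionally with σ scaled
  linearly with the initial strength (σ² by the squared weight-scale).
* `run_population()` — 100 synapses at 200 µm, independent 3 Hz trains,
  each synapse calibrated to an initial somatic EPSP of 0.16 mV
  (`calibrate_weight()` bridges the mV strength unit to conductance);
  strengths at checkpoints are reconstructed through a probe-calibrated
  monotone weight-to-EPSP spline, and synapses stronger than 10 mV are
  excluded from skewness statistics because their EPSPs trigger spikes
  that bias the measurement.

Choices where the emulated procedures were underdetermined: postsynaptic
conditioning spikes are Poisson and delivered through the eliciting-pulse
mechanism; the population experiment uses 10 trials; the depression-window
edge is defined operationally as the largest negative delay whose relative
change is below −1 % (beyond the bAP-driven window the rule still yields a
vanishingly small noise-driven drift, so a strict sign test would be
degenerate), with an interpolated variant for comparisons between sweeps;
crossover points are linear interpolations of the first sign change.

## What the simulations do and do not show

The generator emulates independent stationary Poisson drive onto
equidistant synapses of a passive unbranched cable. Real dendrites are
branched, electrically active, and receive structured, correlated input;
passing these tests therefore shows that the *rule* produces the
spike-timing, frequency, rate, location and metaplasticity phenomenology on
a minimal substrate, not that the quantitative values transfer to a full
morphology. Known limitations, all consequences of the reduction and left
visible rather than patched:

* The depression window does not widen between 200 µm and 400 µm as it
  does with an actively repolarized bAP: in a passive cable the late tail
  relaxes with the membrane time constant at both locations, so the window
  is set by amplitude rather than tail duration.
* In the voltage-clamp protocol the control curve reproduces the null at
  rest and the depression window, but stays a few percent below zero at
  the strongest commands instead of crossing into potentiation: the
  noise-term depression accumulated while $\bar u$ adapts to the clamp
  outweighs the weak potentiation available through clamp escape. With σ
  scaled down (the depressed-synapse variant) the potentiation branch
  appears, and the window-width homeostasis has the right directions.
* A proximal NMDA-only synapse keeps a residual potentiation
  (~1 %/pairing) for +10 ms pairings at very low rates, where the full
  model predicts essentially none.
* Per-trial population skewness is heavy-tailed across trials (s.d. ≈ 2
  over 10 trials), so the 10-trial mean reported for the 300 s experiment
  carries a standard error of roughly 0.6–0.9.

Problem sizes were chosen to keep every experiment at desk scale: 60
compartments, dt = 0.1 ms, 100-synapse populations over 300 s × 10 trials,
and pairing protocols of 7–100 repetitions — the sizes at which the
calibration targets above were evaluated and frozen.

## Reproducing the numbers

```r
library(sparsehebb)

# STDP pairing window (control vs primed)
ctrl <- run_delay_sweep(seq(-40, -5, by = 5))
ltd_window_width(ctrl)                    # ~20 ms

# frequency crossover of post-pre pairings
fs <- run_frequency_sweep(delays = -10)
sign_crossover(fs$frequency, fs$relative_change)   # ~33 Hz

# population skewness after 5 min
pop <- run_population(duration = 300, n_trials = 10, seed = 1)
mean(population_skewness_by_trial(pop, 300))       # ~3.4-4.4
plot(pop)                                          # CDF with lognormal fit
```

`scripts/acceptance.R` packages these four headline quantities (population
skewness, crossover frequency, window width, distance switch) into a JSON
report; see the README for how to run it.
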