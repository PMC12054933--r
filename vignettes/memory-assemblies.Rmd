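---
title: "Modular memory assemblies from Hebbian and anti-Hebbian inhibitory STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular memory assemblies from Hebbian and anti-Hebbian inhibitory STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qifstdp)
```

## The model

`qifstdp` simulates a network of $N$ quadratic integrate-and-fire (QIF)
neurons whose membrane potentials obey

$$\tau_m \dot V_i = V_i^2 + \eta_i + g_e S_i^e + g_{hi} S_i^{hi}
  + g_{ai} S_i^{ai} + I_i(t) + \xi_i(t),$$

where $\eta_i \sim \mathcal N(0, (\pi\tau_0)^2)$ are heterogeneous
excitabilities, $I_i$ is a square-pulse stimulation current and $\xi_i$ a
Gaussian noise term. A neuron crossing the threshold $V_p = 10$ emits a
spike at the corrected time $t + \tau_m/V$, is reset to $V_r = -10$ and
held there for $2\tau_m/V$ — the time an exact QIF trajectory needs to
escape to $+\infty$ from $V_p$ and return from $-\infty$ to $V_r$. Each
synapse class drives an exponentially decaying synaptic variable
($\tau_{de} = 2$ ms excitatory, $\tau_{di} = 5$ ms inhibitory) that jumps
by $w_{ij}/N_q$ when pre-synaptic neuron $j$ of class $q$ fires.

Three spike-timing-dependent plasticity rules act on the weights,
selected by the class of the *pre-synaptic* neuron:

* **excitatory — asymmetric Hebbian**: causal pairs
  ($\Delta t = t_{\mathrm{post}} - t_{\mathrm{pre}} > 0$) potentiate,
  anti-causal pairs depress (`lambda_e()`);
* **Hebbian inhibitory — symmetric Ricker wavelet**: near-coincident
  spikes potentiate regardless of order (`lambda_hi()`);
* **anti-Hebbian inhibitory — reversed Ricker wavelet**: coincident
  spikes depress, uncorrelated firing slowly potentiates (`lambda_ai()`).

All three kernels carry a constant forgetting offset $f = f_0/M$
($f_0 = 0.2$, $M$ = number of stored memories), so unused synapses decay.
Updates are event-driven with last-spike pairing and pass through tanh
soft bounds of slope $\lambda = 100$ (`weight_update()`), which confine
excitatory weights to $[0,1]$ and inhibitory ones to $[-1,0]$ without a
hard clip. Excitatory synapses obey Dale's principle throughout.

Under selective stimulation (35 one-second epochs, 800 ms on / 200 ms
relaxation, randomly alternating over target populations), the network
develops modular connectivity: strong intra-assembly excitation, Hebbian
inhibitory neurons wiring *feedback* loops inside each assembly (rate
control), and anti-Hebbian neurons wiring *lateral* connections between
assemblies (competition/selectivity). After training, spontaneous
transient synchronisations of single assemblies — *memory recalls* —
re-potentiate the assembly's weights against the forgetting drift.

## Numerical scheme and the noise discretisation

The equations are integrated with a stochastic Euler scheme at
$dt = 1$ ms. The one genuinely open numerical choice is how to
discretise $\xi_i(t)$, and the package exposes three readings
(`network_params(noise_mode = ...)`):

* `"step"`: a fresh draw $\mathcal N(0, \sigma^2)$ each step, applied
  like the deterministic terms. The effective noise is tiny
  ($\propto dt/\tau_m$): sub-threshold neurons essentially never fire.
* `"em"`: Euler–Maruyama, treating $\xi$ as white noise of intensity
  $\sigma^2$. The noise dominates the excitabilities: every neuron fires
  at several hertz.
* `"pc"` (default): the draw is held piecewise-constant over one
  membrane time constant, i.e. the noise fluctuates on the timescale the
  membrane can follow. Numerically this is $\sqrt{\tau_m/dt} \approx 4.5$
  times stronger than `"step"` and an order of magnitude weaker than
  `"em"`, with the reference amplitude $\sigma = 4\pi\tau_0$ unchanged.

The default was calibrated against the stated resting statistics of the
model, not fitted to any acceptance threshold: with `"pc"` the untrained
network rests near 1 Hz with spontaneous rates spread over a few hertz
(the stated "firing variability" of a few Hz), stimulated populations
fire at 50 Hz, the all-Hebbian training regime relaxes to about 1 Hz,
and the all-anti-Hebbian regime shows the winner-takes-all pathology.
Trained networks exhibit balanced spontaneous recalls in both
assemblies.

The choice has real consequences, which we report openly. Under `"step"`
the resting background is so sparse that the *imperfectly learned*
two-module matrix (intra 0.7/−0.7, truncated-Gaussian inter weights)
never ignites a recall: over 2000 simulated seconds the intra-module
weights only decay. Under `"em"` that same matrix consolidates exactly
as described — recalls every few hundred milliseconds, intra E→E mean
weight rising from 0.70 to above 0.8 within 300 s, a 2 Hz peak in the
population-rate distribution — but the pre-training resting rate
inflates to ~4.4 Hz and the winner-takes-all regime disappears. No
single reading we scanned (per-step multipliers 1–24 and full white
noise) reproduces both the quiet resting state and the bootstrap of
consolidation from the 0.7 template; `"pc"` preserves the quiet-state
phenomenology and trained-state recalls, at the cost of the
template-bootstrap observables (the rate-distribution mode stays at
0 Hz and the per-module order parameter near 0.16 rather than 0.4).
The `"em"` cross-check demonstrates that the consolidation machinery
itself — detector, plasticity, maintenance balance — is implemented and
functional.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau_m` | 0.02 | s | membrane time constant |
| `tau_de`, `tau_di` | 0.002, 0.005 | s | synaptic decay (E, I) |
| `ge`, `ghi`, `gai` | 100, 200, 400 | – | class coupling strengths |
| `eta_sd` | $\pi\tau_0$ | – | excitability spread (0–8 Hz rates) |
| `noise_sigma` | $4\pi\tau_0$ | – | noise amplitude |
| `stim_amplitude` | $(50\pi\tau_0)^2$ | – | DC current (≈50 Hz response) |
| `A_plus`, `A_minus` | 5.296, 2.949 | – | asymmetric-kernel amplitudes |
| `A`, `tau` | 3, 0.1 s | – | Ricker kernel amplitude/width |
| `f0` | 0.2 | – | forgetting scale, $f = f_0/M$ |
| `gamma_l` | 0.005 | – | learning rate |
| `lambda` | 100 | – | soft-bound slope |

One description of the model lists `ghi = 400, gai = 200`; its
parameter table lists `ghi = 200, gai = 400`. The package follows the
table and exposes both knobs so the alternative can be tested.

## What the generator emulates — and what it does not

All inputs are synthetic by design: the model's "data" are its own
dynamics. `init_network()` draws excitabilities and small random initial
weights (uniform up to 0.05 in magnitude — the reference description only says
"small"); `build_modular_matrix()` constructs the imperfectly learned
template; `build_stimulus_schedule()` builds the training protocols
including the untrained-population, random-subset and amplitude-jitter
variants; `randomize_weight_subset()` produces the damage/recovery
initial conditions. Passing tests therefore show internal consistency of
the model under its stated conditions, not agreement with biological
recordings: there are no transmission delays, no conductance-based
synapses, no spatial embedding, and the all-to-all (or Erdős–Rényi)
coupling is an idealisation.

## Indicators

* `instantaneous_rate()` — spike counts over $T = 0.05$ s windows.
* `coefficient_of_variation()` — ISI CV per neuron; at least 10 ISIs are
  required by default so refractory-forced regularity on two or three
  spikes is not reported as a CV.
* `spike_phases()` / `kuramoto()` — phases interpolated linearly between
  consecutive spikes; outside a neuron's first/last spike the phase is
  undefined and the neuron is *excluded* from $Z(t)$ at those times
  (freezing the phase instead would manufacture coherence among silent
  neurons).
* `weight_change_rate()` — $K(t)$ over snapshot pairs 0.1 s apart,
  normalised by $N(N-1)$; positive under net potentiation.
* `detect_recalls()` — sliding 0.2 s window; an event is attributed to a
  module when more than half of its exclusive excitatory neurons spike
  in the window while every other module stays at or below that
  fraction (the window length is specified but not the fraction; 0.5 is the
  package default and is reported with every verdict). Windows with two
  or more modules above threshold are flagged `joint`.
* `classify_stability()` — stable iff the time-median network order
  parameter stays below 0.5, the population rate below 20 Hz, and every
  module shows at least one recall over the horizon. The ceilings are
  motivated by the asynchronous-state statistics ($R$ fluctuating around
  0.2, rates peaked at 2 Hz) and are configurable.
* `forgetting_time_estimate()` — the S-curve balance behind maintenance:
  mean weight boost of one recall volley divided by the mean drift per
  second of an excitatory synapse between two independent 2 Hz Poisson
  neurons. The volley model (two near-coincident spikes per neuron at
  the within-event rate of ~15 Hz, ±10 ms jitter) mirrors the elevated
  rates observed during transient synchrony events; both quantities are
  evaluated at mid-range weight where the soft bounds are inactive.

## Design choices on open points

* **Spike pairing** is nearest-spike (last spike) only; a synapse whose
  partner has never fired is skipped, since $\Delta t$ is undefined.
  Spikes within one Euler step are processed in corrected-time order, so
  a volley pairs each neuron with the partner's in-volley spike.
* **$f = f_0/M$ is applied to all three kernels.** The scaling is stated
  for the excitatory kernel; at the reference $M = 2$ all three equal
  the reference $f = 0.1$, so the choice is invisible there and each
  kernel's `f` remains an independent knob.
* **Refractory expression**: the hold duration is stated
  ambiguously; we read it as $2\tau_m/V$ evaluated at the crossing value
  $V$, and expose the factor as `refractory_scale`.
* **Sparse connectivity** uses a directed Erdős–Rényi mask applied
  multiplicatively; masked synapses are excluded from plasticity and the
  normalisation constants stay $N_q$ (not the in-degree).
* **Capacity-scan horizon**: stability is assessed on 120 s of resting
  dynamics from the pre-built template (no reference value exists for the
  duration per grid point); `capacity_scan(horizon = ...)` overrides it.
  Recovery experiments likewise run scaled horizons (minutes standing in
  for hours of real time); long-run parity is an extrapolation, not an
  assertion.
* **Problem sizes in the tests**: the shipped suite and the acceptance
  script use $N = 100$ runs of up to 300 s, one $N = 1000$ run of 60 s
  and a 120 s capacity confirmation — sizes chosen so the whole suite
  completes in a few minutes while keeping every measured quantity at
  the stated operating point.

## Known limitations

* The template-bootstrap observables (per-module order parameter ≈ 0.4,
  2 Hz rate mode, growing intra-module weights from the 0.7 template)
  are not reproduced under the default noise reading; see the noise
  section above and the package's acceptance documentation.
* The maximal-capacity configuration ($M^\star = N/3$, one excitatory
  neuron per memory) passes the counting rule and the asynchrony check,
  but under the default conditions a few of the 33 single-neuron modules
  show no exclusive recall within 120 s.
* The $N = 1000$ background rate (~0.3–0.4 Hz) already fills 0.2 s bins
  to ~10–15% of $N$ at their maximum, above the reference ≤5% bound,
  which would require a background below ~0.17 Hz.
* Long-horizon claims (hours of consolidation, 24 h recovery) are
  extrapolated from minutes-long runs.

## A worked example

```{r example, eval = FALSE}
library(qifstdp)
exp <- training_experiment(regime = "mixed", M = 2, seed = 1)
stats <- module_weight_stats(exp$weights, neuron_classes(exp$params),
                             module_vector(exp$assignment))
stats
recalls <- detect_recalls(exp, exp$assignment,
                          t_start = exp$phases["learning_end"])
table(recalls$label)
```

After the 5 s rest / 35-epoch learning / 20 s consolidation protocol the
block means show the signature structure (intra E→E near 1, inter near
0; Hebbian inhibition intra-concentrated, anti-Hebbian
inter-concentrated), and the post-learning raster contains spontaneous
recalls of both assemblies.
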