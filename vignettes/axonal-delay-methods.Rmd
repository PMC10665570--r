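---
title: "Spiking networks with learnable axonal delays: models, losses and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking networks with learnable axonal delays: models, losses and training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axodelay)
```

## The neuron model

`axodelay` simulates discrete-time Spike Response Model (SRM) neurons. The
membrane potential of neuron $i$ in layer $l$ is

$$u_i^l(t) = \sum_j W_{ij}^{l-1} (\epsilon * s_j^{l-1})(t) + (\nu * s_i^l)(t) + b_i,$$

the weighted sum of input spike trains filtered by the response kernel
$\epsilon(t) = (t/\tau_s)\,e^{1 - t/\tau_s}\,\Theta(t)$ plus the neuron's own
output spikes filtered by the refractory kernel
$\nu(t) = -\alpha_r \theta_u (t/\tau_r)\,e^{1 - t/\tau_r}\,\Theta(t)$. A spike
is emitted whenever $u \ge \theta_u$; ties fire, because the Heaviside at zero
is conventionally one. The kernels vanish at lag zero, so a spike influences
the membrane only from the following step on, which makes the time loop
well-defined without implicit equations.

Parameters and units: $\tau_s$, $\tau_r$ are in simulation steps of $T_s$
(1 ms by default), $\theta_u$ is in mV (10 mV default), $\alpha_r$ is
dimensionless (2 by default; the refractory kernel bottoms out at
$-\alpha_r \theta_u$). The discretized kernels are truncated at
`kernel_window` steps, defaulting to $8\max(\tau_s,\tau_r)/T_s$, where the
neglected tail is below $10^{-3}$ of the kernel peak.

One modelling choice deserves a note: every fully-connected layer carries one
learnable bias per neuron. Published parameter counts for this family of
architectures (e.g. 26,251 for a 64–128–128–11 stack) are reproduced exactly
only with that bias, so `count_parameters()` includes it.

## Learnable axonal delays

Each neuron of a delay-equipped (VAD) layer owns one integer axonal delay: a
spike emitted at step $m$ reaches every downstream synapse at step
$m + d_i$. Delays are trained on a continuous "shadow" value (the Adam state)
and projected after every update:

$$d_i = \min(\max(0, \lfloor \hat d_i / T_s \rfloor), \theta_d).$$

Rounding is *down* by default (a `nearest` mode exists as a config switch),
the cap $\theta_d$ is per-layer config, and all delays start at zero. Spikes
shifted past the fixed observation horizon are dropped rather than extending
the raster, which keeps the loss normalization of a fixed $(N_s+1)T_s$ window
intact.

The delay gradient uses a finite-difference estimate. Writing the delayed
train as $s_d(t) = s(t - d)$, the chain rule needs $\partial s_d[m]/\partial d
= -s'(t-d) \approx -(s_d[m] - s_d[m-1])/T_s$, so

$$\frac{\partial L}{\partial d_i} = \sum_m \big(s_d[m-1,i] - s_d[m,i]\big)\,
\frac{\partial L}{\partial s_d[m,i]},$$

with $s_d[-1] = 0$ and the upstream factor accumulated over all later time
steps by backpropagation through time. The sign convention is fixed by the
requirement that the estimator descend the loss: the package verifies it
against central numerical differences of a smoothed alignment loss under
$\pm 1$-step shifts (see the delay test file), where the implemented form
agrees in sign on every informative unit and the opposite sign would agree on
none. Because the estimator is a one-step difference, its per-sample value
far from any loss-relevant alignment is noisy; batch averaging is what makes
delay learning effective, and the recovery experiment below is designed with
that in mind.

Gradient flow to the weights passes through the shifted raster as if the
shift were a constant — the delay module is a pure re-indexing in the
backward pass.

## Local skip-connections

A local skip-connection re-processes a layer's delayed output spikes through
a square synaptic map $V$ with its own SRM pass,

$$\hat u_i^l(t) = \sum_j V_{ij}^l (\epsilon * s_{d,j}^l)(t) + (\nu * \hat s_i^l)(t),$$

and the combined train $s^l = s_d^l + \hat s^l$ feeds the next layer's shared
weights. The combined train may contain a 2 where a delayed and a local spike
coincide; since the $\epsilon$-convolution is linear this simply counts two
coincident spikes, and no clamp is applied. Local spikes are not re-delayed,
and the local neuron keeps its own refractory state, independent of the
neuron whose spikes it re-processes. The purpose of the construction is to
compensate for information lost to the post-spike reset: at large $\alpha_r$
a neuron that has just fired cannot respond again for a while, and the local
pass can re-emit the information on the same axon line.

## Objectives

**Spike-rate loss.** Classification reads out spike counts over the window.
Every readout neuron has a class-dependent target count — `target_true` for
the labeled class, `target_false` for the rest — and

$$L = \sum_i \tfrac12\big(\textstyle\int \tilde s_i - \int s_i\big)^2
    = \sum_i \tfrac12 (\text{target}_i - \text{count}_i)^2 .$$

The per-neuron sum with class-dependent targets is the only reading under
which a count-targeting loss trains a $C$-way classifier. The numeric targets
are nowhere fixed by the model family, so they are configuration: the
defaults (30/5 over a ~300-step window; 12/2 for the ~120-step synthetic
task) keep the true-class target well below the refractory-limited maximum
firing rate while staying clearly above the background.

**Suppressed-membrane loss.** To sharpen decisions, wrong-class readout
neurons are penalized at the instants they fire, through their pre-spike
membrane:

$$L_{Mem} = \sum_{t,i} \tfrac12\big(s[t,i]\cdot \text{mask}_i \cdot
(u[t - \Delta t, i] - u_\theta)\big)^2, \qquad u_\theta = \lambda_u \theta_u,$$

with $\Delta t$ equal to one simulation step and the mask zero at the true
class, one elsewhere. With $\lambda_u = 0.995$ and $\theta_u = 10$ mV, a
false neuron firing with pre-spike membrane 12 mV contributes
$\tfrac12(12 - 9.95)^2 = 2.10125$. The backward pass uses the membrane path
only, $\partial L_{Mem}/\partial u = s \cdot \text{mask} \cdot (u - u_\theta)$
(the binary factors square to themselves); no surrogate path through the
spike factor is taken. The term acts as a soft winner-takes-all regularizer
and is invariant to the true neuron's membrane by construction.

**Delay regularizer.** An optional penalty confines delay magnitudes. Whether
"an L2 regularizer on $\sum_i \hat d_i$" means $\sum \hat d_i^2$ or a penalty
on the (non-negative) sum itself is genuinely ambiguous, so both are exposed:
`l2_mode = "squared"` (the default, coefficient times the squared norm of the
shadows) and `"sum"`. It is applied to the continuous shadows so that it is
differentiable; projection still runs afterwards.

## Training

Training is surrogate-gradient backpropagation through time with a single
global Adam group (learning rate 0.1 by default, shared by weights, biases,
local weights and delay shadows), delay projection after every optimizer
step, and per-batch averaging of per-sample gradients. The backward pass
replaces the Heaviside derivative with the exponential proxy

$$f_s' = \tau_{scale} \exp(-|u - \vartheta| / \tau_\vartheta),$$

$\vartheta = \theta_u$. Neither proxy parameter is part of the model family's
published settings; the package defaults are $\tau_{scale} = 1$ and
$\tau_\vartheta = 1$ mV, a deliberately narrow width.

Two numerical choices matter enough to spell out:

* **Refractory feedback in the backward pass.** Unrolling the reset term's
  gradient ($u[t+k] \leftarrow \nu[k]\, s[t]$) is analytically exact — the
  package verifies its own implementation of it against numerical central
  differences in a smoothed regime — but in hard-threshold training the
  backward loop gain $|\nu| \cdot f_s'$ (with $\nu$ reaching $-\alpha_r
  \theta_u = -20$ mV) systematically corrupts weight gradients: on a trivially
  separable task, training with the full path collapses, while treating the
  reset drive as a constant trains to perfect accuracy. The training default
  is therefore `refr_grad = "detached"`, the convention of the surrogate
  formulation this package adopts; `"full"` remains available and is what the
  gradient-verification tests exercise.
* **Smooth verification mode.** Because the hard threshold makes numerical
  differentiation of the real forward pass meaningless, gradient correctness
  is verified in a `soft = TRUE` mode that replaces the Heaviside with the
  smooth function whose derivative is (half) the surrogate. In that regime
  the surrogate is the exact derivative, so analytic BPTT must agree with
  central differences to numerical precision — and does, including through
  the refractory recurrence. This separates "is the calculus right" from "is
  the proxy a good idea", which the task-level experiments answer.

**Two-phase protocol.** When the suppressed loss is enabled, training first
runs `pretrain_epochs` epochs (20 by default) on the rate loss alone; the
pretraining fixes the spike-count targets and which neurons count as
true/false before the membrane penalty switches on. The phase boundary is
configurable.

Divergence (non-finite loss) aborts with a diagnostic rather than silently
producing NaN parameters. Given identical seeds, training is bit-reproducible:
the seed controls initialization, shuffling and the synthetic data.

## Event data input

Readers exist for the two event-audio formats this model family targets:
SHD-schema HDF5 (ragged `spikes/times` in seconds, `spikes/units`, `labels`;
700 channels, 20 classes) and plain-text event lists (one `time_ms channel`
pair per line, one file per sample; the 64-channel, 11-class silicon-cochlea
digits layout). Times are ms internally; SHD seconds are converted on load.
Because the available R HDF5 bindings cannot read ragged datasets, HDF5
traffic goes through a bundled helper run by the system Python with `h5py`;
the same bridge writes miniature SHD-schema fixtures so the full read path is
exercised offline. `bin_events()` converts events to fixed-horizon rasters:
floor binning (a boundary event goes to the later bin), at most one spike per
channel per bin, zero-padding short samples and truncating long ones —
mirroring the benchmarks' preprocessing, where SHD is resampled to 4 ms bins
and channels carry at most one spike per bin. Dataset files are never fetched
automatically; loaders take local paths, and all tests run on bundled
synthetic fixtures.

## The synthetic coincidence task

The generator emulates the one property of event-based speech that makes
axonal delays valuable — class identity carried by *inter-channel timing* —
at a scale where full training runs take seconds. Each sample is background
Bernoulli noise (`base_rate` per step and channel) plus `n_repeats`
occurrences of a planted pattern: at each random anchor, channel $j$ fires at
anchor $+$ `offset_table[class, j]`, jittered by rounded Gaussian noise.
Anchors are uniform, so marginal channel rates are class-independent; only
relative lags separate the classes. The default offset table
$(c \cdot j) \bmod (\text{max\_offset}+1)$ gives every class a distinct and
*non-synchronous* pattern — with a synchronous class in the table, a plain
feedforward network detects it by coincidence strength alone, which blunts
the contrast the task exists to probe. A brute-force
delay-and-coincidence classifier (`oracle_classify()`) is exact on a clean
instance by construction and serves as the separability oracle.

The packaged study conditions (`coincidence_task()`) go one step further:
the three classes are a rising ramp of lags, the reversed ramp, and a zigzag
of the *same* lag values — one shared multiset of pairwise lag magnitudes,
differing only in which channel leads which. A network without delays can
read lag magnitudes through the amplitude of overlapping post-synaptic
potentials, and pilot versions of the task that left that channel open were
solved nearly as well without delays; order information is what the delay
module specifically provides. Pattern events are 3-step bursts rather than
single spikes, both because cochlear channels respond to band energy with
short spike trains and because bursts give the one-step finite-difference
delay gradient a usable attraction basin (see below).

What the generator does *not* emulate: cochlear tonotopy and band
correlations, sample-length variability, rate modulation within a word, and
speaker variability. Passing the miniature experiments therefore demonstrates
that the training machinery works and that the delay/local/suppressed
components interact as designed — not that any particular accuracy carries
over to real recordings.

**Study conditions.** The packaged experiments run at: 3 classes, 6 channels,
120 steps, base rate 0.02, lags 0–15 in steps of 3, jitter SD 0.5 steps,
3-step bursts, 3 pattern repeats, 60 training and 30 test samples; one hidden
layer of 12 neurons, $\tau_s = \tau_r = 2$, $\alpha_r = 2$, $\theta_d = 24$;
batches of 10, 30 epochs, count targets 12/2, the default narrow surrogate.
These sizes were chosen once, as the smallest instance in which the planted
lags exceed the response kernel's effective support (so delays are genuinely
load-bearing) while multi-seed training remains a matter of minutes on one
CPU core.

**Delay recovery.** The parameter-recovery experiment plants a single lag
$k$ between two channels and trains only the delays
(`delay_recovery_experiment()`). Design notes, since the one-step
finite-difference gradient shapes all of them: the first layer runs without
refractory so each input spike becomes a short burst, which widens the
coincidence basin from $\pm 2$ to roughly $\pm 10$ steps; the readout weights
are frozen low enough that one channel's burst cannot reach threshold alone,
making the spike count grow with burst overlap; and the count target is set
slightly above the best attainable count so the pull toward alignment never
switches off as the optimum is approached. With those choices, gradient
descent recovers planted lags of 2–10 steps to within one step across seeds.

## Named experiments and parameter accounting

`resolve_experiment()` maps the published architecture names (`D128-SNN`,
`DL128-SNN`, `DL128-SNN-Dloss`, `DL256-SNN-Dloss`, `DL128-SNN-Dloss-L2`, and
the plain/local-only baselines) to full configurations per dataset profile:
the cochlea-digits profile ($\tau_s=\tau_r=5$, $\theta_d=128$, 64 channels,
11 classes) and the SHD profile ($\tau_s=\tau_r=1$, $\theta_d=64$, 700
channels, 20 classes), both with batch 128, learning rate 0.1,
$\lambda_u = 0.995$. `count_parameters()` reproduces the full published
ablation parameter grid from these names alone: a dense layer contributes
$n_{in} n_{out} + n_{out}$, a VAD module $n_{out}$, a local skip-connection
$n_{out}^2 + n_{out}$.

Full-scale benchmark training (hours of CPU/GPU on the downloaded datasets)
is out of scope for the test suite; the `ablate` CLI command and the
miniature synthetic grid are the in-package analogue, asserting the
*direction* of the ablation (delays help; local connections do not hurt and
stabilize large-$\alpha_r$ regimes) rather than external-data magnitudes.

## Known limitations

* Dense matrix simulation: rasters are dense `n_steps × n_units` matrices;
  fine for hundreds of channels and steps, wasteful for very sparse streams.
* Per-neuron (axonal) delays only; per-synapse (dendritic) delays, learnable
  delay caps and fractional-delay interpolation are out of scope.
* The finite-difference delay gradient is local: isolated single-spike
  trains give it a narrow basin, and tasks relying on it should provide
  temporally extended activity (bursts, overlapping kernels) or expect
  slower, noisier delay learning.
* The readout is spike-count argmax with lowest-index tie-breaking; no
  spike-time or likelihood readouts.
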