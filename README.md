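# axodelay

Spiking neural networks in which every neuron carries a **learnable integer
axonal delay**, implemented and trainable entirely in R.

## The problem

Event-based audio — spoken digits encoded as spike trains by silicon or
simulated cochleas — carries its class information in *when* channels fire
relative to each other, over spans of tens to hundreds of milliseconds.
Feedforward spiking networks with millisecond-scale synaptic kernels cannot
integrate across such spans: information arriving at the wrong moment is
simply gone. A per-neuron axonal delay lets the network *re-align* spike
trains so that related events become coincident, turning long-range temporal
structure into something a threshold neuron can detect. This package is for
researchers who want a compact, fully inspectable implementation of that
idea: discrete-time Spike Response Model (SRM) dynamics, trainable delays
with a finite-difference gradient, local skip-connections that compensate
for post-spike reset, and a spike-rate objective with an auxiliary
suppressed-membrane penalty.

## The model

Membrane potential of neuron $i$ in layer $l$:

$$u_i^l(t) = \sum_j W_{ij}^{l-1}(\epsilon * s_j^{l-1})(t) + (\nu * s_i^l)(t), \qquad
s_i^l(t) = \Theta(u_i^l(t) - \theta_u)$$

with response kernel $\epsilon(t) = (t/\tau_s)e^{1-t/\tau_s}$ and refractory
kernel $\nu(t) = -\alpha_r \theta_u (t/\tau_r) e^{1-t/\tau_r}$. Each
delay-equipped neuron shifts its output train by an integer number of steps,
$s_d^l(t) = s^l(t - \hat d)$, with $\hat d$ trained on a continuous shadow
value, clipped to $[0, \theta_d]$ and rounded down after every optimizer
step. The delay gradient is the backward finite difference of the delayed
train times the backpropagated error. A local skip-connection re-processes
the delayed spikes through a square map $V$ and sends $s_d + \hat s$ down
the same axon line. Training is surrogate-gradient BPTT with Adam; the
readout is the spike-count argmax, optionally regularized by a penalty on
wrong-class neurons' pre-spike membranes
($u_\theta = \lambda_u \theta_u$).

## A worked example

Train the delay-plus-local-skip variant on the packaged synthetic
coincidence task, where three classes differ only in which cochlear channel
leads which:

```r
library(axodelay)

task  <- coincidence_task(seed = 1)
data  <- generate_synthetic(task)
srm   <- srm_config(tau_s = 2, tau_r = 2, alpha_r = 2, theta_u = 10)
spec  <- network_spec(list(
  layer_spec(6, 12, vad = TRUE, local = TRUE, theta_d = 24),
  layer_spec(12, 3)), n_classes = 3, srm = srm)
model <- build_network(spec, seed = 1)

fit <- train_network(model, data$train,
                     train_config(lr = 0.1, batch_size = 10, epochs = 30,
                                  pretrain_epochs = 30, seed = 1),
                     loss_config(target_true = 12, target_false = 2))
evaluate_network(fit$model, data$test)
#> [1] 0.9333333
delay_histogram(fit$model)$layer1
#>  0  1  2  3  4  5  6  7  8  9 10 11 12 13 14 15 16 17 18 19 20 21 22 23 24
#>  5  0  2  2  0  0  1  1  0  1  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0
```

93% of held-out samples are classified correctly, and the delay histogram —
all mass at 0 before training — has spread: different hidden neurons now
listen at different lags, which is exactly the mechanism under study. The
same run without the delay module (`vad = FALSE, local = FALSE`) reaches
about 80–87% depending on seed; `ablation_experiment()` runs that comparison
systematically over seeds.

Parameter accounting for the full-scale architectures reproduces the
published grid from the architecture names alone:

```r
count_parameters(resolve_experiment("D128-SNN", "ntidigits")$network)
#> [1] 26507
count_parameters(resolve_experiment("DL128-SNN", "shd")$network)
#> [1] 142100
```

A command-line interface wrapping these functions ships at
`inst/cli/axodelay.R`
(`train`, `evaluate`, `ablate`, `sweep-refractory`, `count-params`,
`make-synthetic`, `make-fixture`).

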