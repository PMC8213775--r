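---
title: "Exact gradients for spiking networks: model, adjoint system, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact gradients for spiking networks: model, adjoint system, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventprop)
```

## The model

The package simulates a recurrent network of $N$ leaky integrate-and-fire
(LIF) neurons as a *hybrid dynamical system*: continuous flow between
spikes, discrete state transitions at spikes. Between events the membrane
potentials $V$ and synaptic currents $I$ obey

$$\tau_\mathrm{mem} \dot V = -V + I, \qquad \tau_\mathrm{syn} \dot I = -I,$$

with zero leak potential and $V(0)=I(0)=0$. When a firing neuron $n$
reaches the threshold $\vartheta$ with $\dot V_n \neq 0$, its potential is
reset to zero and every neuron's current jumps by the corresponding entry
of column $n$ of the recurrent weight matrix $W$ (zero diagonal — no
self-connections). Fixed input spike trains act the same way through the
input weight matrix. Feed-forward architectures are block-structured
special cases of $W$; non-firing leaky-integrator readouts are neurons
excluded from threshold detection.

Because both ODEs are linear, the flow has a closed form (a double
exponential for $V$), so the simulator is *event-driven*: it never
time-steps. Threshold crossings are found by bracketing the closed form on
a grid and refining the bracketed root; events are processed from a merged
queue in time order.

## Exact gradients through spike discontinuities

Losses may depend on spike times ($l_p$) and/or on membrane potentials
($l_V$). The gradient of the total loss with respect to a weight $w_{ji}$
(from neuron $i$ into neuron $j$) is obtained with the adjoint method for
hybrid systems: a pair of adjoint variables $(\lambda_V, \lambda_I)$ is
integrated *backward* in time from $\lambda_V(T)=\lambda_I(T)=0$,

$$\tau_\mathrm{mem} \lambda_V' = -\lambda_V - \partial l_V/\partial V,
\qquad \tau_\mathrm{syn} \lambda_I' = -\lambda_I + \lambda_V,$$

(primes are reverse-time derivatives), and at each recorded spike the
firing neuron's $\lambda_V$ jumps by

$$\frac{1}{\tau_\mathrm{mem}\dot V^-}\left[\vartheta\,\lambda_V^+ +
\big(W^\top(\lambda_V^+-\lambda_I)\big)_n +
\partial l_p/\partial t^\mathrm{post}\right],$$

where $\dot V^- = (-\vartheta + I^-)/\tau_\mathrm{mem}$ is the pre-reset
slope cached by the forward pass. All other adjoint components are
continuous across the event. The weight gradient is then an event-local
sum,

$$\frac{d\mathcal{L}}{dw_{ji}} = -\tau_\mathrm{syn}
\sum_{\text{spikes from } i} (\lambda_I)_j,$$

and input weights sample $\lambda_I$ at their fixed arrival times. These
gradients are *exact* — no surrogate derivative, no smoothing — wherever
the spike pattern is locally stable in weight space. The backward pass
consumes only the spike record and the loss jump schedule, so its memory
scales with the number of spikes, not with a dense state history.

The jump denominators $\dot V^-$ expose the method's intrinsic
singularity: where a spike is about to appear or disappear (membrane
tangent to threshold) the gradient diverges. The package warns when
$|\dot V^-|$ falls below `eps_crit` ($10^{-8}$ by default) rather than
clipping, since training works without clipping; an optional report of
such events is part of each gradient call.

## Loss heads

**First-spike-time cross-entropy** (`ttfs_head`): per sample, with
$t_k$ the first spike time of output neuron $k$ and $l$ the label,

$$l = -\log\mathrm{softmax}(-t/\tau_0)_l +
\alpha\big(e^{t_l/\tau_1} - 1\big).$$

The first term depends only on spike-time differences; the second is a
positive penalty on late label spikes (it *encourages early spiking* — a
formulation where the leading minus sign also covered the regularizer
would reward arbitrarily late spikes and be unbounded below, so the
penalty sign follows the term's stated purpose). Sensitivities attach to
each output neuron's first spike only. Defaults $\tau_0 = 0.5$ ms,
$\tau_1 = 6.4$ ms, $\alpha = 3\times10^{-3}$ are the published task
values.

A neuron that never fires enters the softmax as $e^{-\infty} = 0$ and has
no spike to attach a sensitivity to. When the *label* neuron is silent
the sample's gradient is zero and a constant `missing_penalty` (default
100) is reported as its loss — a documented heuristic: the published
experiments avoid this case via non-quiescent initialization, and nothing
in the sources specifies it. The constant only affects the reported loss,
never the gradient.

**Max-over-time voltage cross-entropy** (`max_voltage_head`): softmax
over each non-firing readout's maximum membrane potential. Each readout's
maximum time $t^*_k$ becomes a Dirac-style voltage-loss jump of
$\lambda_V$ during the backward sweep, of magnitude
$(\mathbf{1}[k=l] - \mathrm{softmax}_k)/(\tau_\mathrm{mem} N_\mathrm{batch})$
in the backward-sweep direction (a unit voltage delta contributes
$1/\tau_\mathrm{mem}$; terms containing the derivative of the delta
vanish because $\dot V(t^*) = 0$ at an interior maximum). The maximum is
computed per inter-event segment from the analytic extremum of the double
exponential, compared with segment endpoints; ties resolve to the
earliest time, and a maximum falling exactly on an event boundary is
scheduled at that event and processed before the event's other backward
actions — a measure-zero case that needs a deterministic rule for
replay.

## Numerical choices

* **Units.** Milliseconds throughout; $\vartheta = 1$ (voltages in
  threshold units).
* **Root finding.** Brackets are declared only on a sign change of
  $V - \vartheta$ on a grid of $\tau_\mathrm{syn}/20$; the root is then
  bisected to machine precision (~52 iterations from a 0.25 ms bracket).
  Bisection is unconditionally robust for a bracketed sign change and the
  closed form is cheap. Event times resolved to machine precision keep
  the noise floor of finite-difference comparisons near $10^{-12}$,
  which the exactness checks need. Tangential touches (a membrane peaking
  exactly at threshold) produce no sign change and are deliberately
  non-events: the transition condition requires $\dot V \neq 0$ and the
  critical set has measure zero.
* **Simultaneous events.** At numerically equal times: input spikes
  first, then threshold crossings in ascending neuron index, each using
  the pre-transition currents (current jumps commute, so the state is
  order-independent; the rule makes replay bit-deterministic). The
  backward sweep mirrors this order in reverse, with voltage-loss jumps
  first; coincident spikes apply their adjoint jumps from a common
  pre-jump $\lambda_V$ snapshot.
* **Degenerate inputs.** $\tau_\mathrm{mem} = \tau_\mathrm{syn}$ (the
  alpha-kernel limit) is rejected rather than special-cased. A runaway
  guard aborts simulations beyond `spike_cap` ($10^6$) events.
* **Horizon.** The Yin-Yang task uses $T = 2\,t_\mathrm{max} = 60$ ms:
  all informative first spikes occur well before this, and the adjoint
  pass is exact for any horizon containing them.

## Verification strategy

Three mutually independent computations cross-check each other in the
test suite:

1. the event-driven forward pass + reverse adjoint sweep (the
   implementation, in compiled code, with a pure-R reference of the same
   semantics);
2. dense explicit-Euler integration of the forward hybrid system, whose
   spike times must converge linearly in the step size to the
   event-driven ones;
3. central-difference gradients from perturbed full simulations.

Finite differences are only meaningful at non-critical points, so the
differencer carries a mandatory spike-count guard: entries where a
perturbation changes any neuron's spike count are flagged and excluded
rather than averaged. The default step is $10^{-4}\max(|w|, 1)$
(exactness experiments use $10^{-5}$); comparisons are relative for
entries within three orders of magnitude of the dominant gradient and
absolute below that, since the relative error of a vanishing entry only
measures the differencer's noise floor.

The bouncing-ball fixture (closed-form ballistic flight, inelastic
reflection with restitution 0.8) exercises the same
implicit-function-theorem jump machinery in two dimensions where every
quantity is known exactly: the position-derivative ratio across the first
impact is $-0.8$, the velocity derivative jumps by
$-0.8\,\partial_v - 1.8\,g\,\partial_y/v^-$, and the impact-time
derivative is $-\partial_y/v^-$.

## The synthetic benchmark

`generate_yinyang()` rejection-samples points uniformly on a disc split
into two interlocking comma-shaped lobes plus two small "dot" discs
(radii 0.5 and 0.1, the reference constants of the benchmark), keeping
points in round-robin class order so classes are exactly balanced. The
class predicate is deterministic and unit-tested against an independent
re-implementation and against the half-turn symmetry that swaps the two
lobes. Points are latency-encoded as $(x, 1-x, y, 1-y)\cdot
t_\mathrm{max}$ on four channels plus a bias spike at $t_\mathrm{bias}$
(defaults 30 ms and 0 ms).

What the generator emulates is the published study's *task*: a 2-D,
three-class, non-linearly-separable problem where a shallow classifier
plateaus near 64% — the spiking network must therefore exploit its hidden
layer and backpropagated errors. What it does not emulate is anything
resembling real sensory data: noiseless coordinates, exactly balanced
classes, five spikes per sample. Passing tests demonstrate correct
gradients and optimization on this geometry, not robustness to natural
variability.

For MNIST-style experiments, pixels with value $\ge 2$ (of 255) are
converted to one spike each; the mapping direction (brighter pixels spike
*earlier*, $t = t_\mathrm{max}(1 - v/255)$) is a convention the sources
leave open — standard intensity-to-latency coding is used, and
`bright_early = FALSE` inverts it. Input spikes can be dropped with
probability `p_drop` during training as regularization. The full MNIST
run requires the external IDX files and hours of CPU; it is wired up
(`read_idx`, `encode_mnist`, `train_voltage_classifier`) but intentionally
not part of any test.

## Training defaults and problem sizes

`train_yinyang()` defaults to the published conditions: 5-200-3
architecture, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, $\eta = 5\times10^{-3}$) with 0.95 per-epoch decay,
minibatch 32, Gaussian initialization with block statistics (hidden:
mean 1.5, sd 0.78; output: mean 0.93, sd 0.1 — read as raw per-weight
parameters, no fan-in scaling, since they are given at block level). The
bias channel's weights are trainable like any other input column. Epoch
counts are not fixed by the sources; the package defaults to 300 and
records train loss, validation accuracy and test accuracy per epoch,
reporting test accuracy both at the best-validation epoch and at the
final epoch (which of the two the published numbers use is unstated, so
both are exposed).

The package's desk-scale configuration — used by the acceptance test — is
120 hidden neurons, 30 epochs, and a 1500/300/1000 split: a run of a few
minutes that reliably clears 90% test accuracy (a single seed reached
96.2%), consistent with the ~96% published for a 120-hidden-unit network
and far above the shallow-classifier ceiling. The full published
configuration (200 hidden, 10 seeds, mean 98.1(2)%) is reproducible with
the defaults but takes correspondingly longer.

## Known limitations

* No refractory periods, adaptive thresholds, conductance synapses,
  transmission delays, or stochastic neurons — the neuron model is the
  plain LIF with exponential current synapses, and
  $\tau_\mathrm{mem} = \tau_\mathrm{syn}$ is unsupported.
* Gradients are exact only away from critical points; learning cannot
  deliberately recruit or dismiss spikes, and near-tangent crossings
  produce large (correct but ill-conditioned) gradients. The package
  warns rather than clips.
* The forward pass detects crossings on a $\tau_\mathrm{syn}/20$ grid; a
  membrane excursion above threshold narrower than one grid cell could in
  principle be missed. With the time constants used here such excursions
  do not occur away from tangency.
* Training is single-threaded and event-driven on CPU; it is meant for
  method-scale experiments, not large-scale deep learning.
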