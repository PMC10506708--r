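---
title: "Model and methods: STDP-driven motion extrapolation in a layered spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: STDP-driven motion extrapolation in a layered spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpnet)
```

## The scientific problem

Neural processing takes time: conduction delays between processing stages
and the integration time of the membrane mean that each level of a visual
hierarchy works on progressively outdated input. For a moving stimulus this
produces *representational lag* — the population-encoded position trails the
stimulus's true position, and the deficit grows with both depth and speed.
`stdpnet` simulates a candidate compensation mechanism: spike-timing
dependent plasticity (STDP) acting on delayed feedforward connections
between velocity-tuned neurons. During motion, presynaptic cells on the
approaching side of a target neuron's receptive field tend to fire before
the target, and cells on the leaving side after it; an antisymmetric STDP
rule therefore strengthens the approaching side and weakens the leaving
side, shifting the receptive field *opposite* to motion. Equivalently, the
population activity — and thus the represented position — shifts *forward*
along the trajectory, partially cancelling the lag. The package measures
how these shifts accumulate across a multi-layer hierarchy and how they
affect realtime position representations.

## Network model

Each of $N_l$ layers holds $N_n$ neurons spatially tuned to equally spaced
points on the circular interval $[0, 1)$ (all positions in "cycles").
Neurons in consecutive layers are connected feedforward only; a connection
from presynaptic neuron $i$ to postsynaptic neuron $j$ exists with
probability $\exp(-d_{ji}^2 / 2\sigma_w^2)$, where $d_{ji}$ is the signed
circular distance between preferred positions. With peak probability 1 this
gives a mean fan-in of $N_w \approx N_n \sigma_w \sqrt{2\pi}$ (about 157 at
the default scale), and weights start at $1/N_w$ plus uniform jitter
$\pm 0.025$ (clipped at zero), so each neuron's incoming sum starts near 1.
Every postsynaptic neuron is guaranteed at least one input (rows are
resampled otherwise), because the multiplicative normalization below is
undefined for a disconnected neuron.

A point stimulus (moving at $v$ cycles/s, or a stationary 20 ms flash)
drives the input layer at rate
$r_j = r_b + 20\, r_b\, \exp(-d_j^2 / 2\sigma_p^2)$ (wrapped), i.e. a
105 Hz peak on a 5 Hz baseline by default; the "magnitude $20 r_b$" is read
as an additive bump so the baseline is always present. Spikes are Bernoulli
with probability $r\,\Delta t$ in every layer — the rule is stated for the
input layer and the same conversion is applied at the higher layers, since
nothing else turns rates into spikes. Higher-layer rates follow a leaky
integration of delayed input,

$$r_j^l(t) = r_j^l(t-\Delta t)\, e^{-\Delta t/\tau_m}
  + \frac{\Delta t}{\tau_m} I_j^l(t), \qquad
  I_j^l(t) = \frac{1}{\Delta t} \sum_i W_{ji}\, S_i^{l-1}(t - t_{delay}),$$

with $\Delta t$ in ms and $I$ in Hz, so $1/\Delta t$ is implemented as
$1000/\Delta t_{\mathrm{ms}}$: a presynaptic population firing at rate $r$
through weights summing to one then drives a steady state of
$r\,(\Delta t/\tau_m)/(1 - e^{-\Delta t/\tau_m}) \approx 1.05\, r$ at the
defaults. This unit convention is isolated in one place and pinned by a
closed-form steady-state test at $10^{-12}$ relative tolerance.

Default parameters (all changeable through `network_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_neurons` | 2000 | neurons per layer |
| `n_layers` | 6 | depth of the hierarchy |
| `sigma_w`, `sigma_p` | 1/32 | connectivity / input activation width (cycles) |
| `r_b` | 5 Hz | baseline input rate |
| `t_delay` | 20 ms | transmission delay per hop |
| `tau_m` | 10 ms | membrane time constant |
| `dt` | 1 ms | timestep |
| `c_p`, `c_d`; `tau_p`, `tau_d` | 1; 20 ms | balanced STDP kernel |
| `n_train_steps` | 20000 | training duration (ramped learning rate) |
| `lr_max` | 4e-4 | plateau learning rate (ramp over first quarter) |
| `norm_prob` | 0.01 | per-step probability of a normalization event |
| `ceiling_factor` | 3 | growth ceiling, × max starting weight |
| `n_runs` | 10 | independent runs averaged per velocity |

## Plasticity

The STDP kernel is
$F(\Delta t) = c_p e^{-\Delta t/\tau_p}$ for $\Delta t > 0$, exactly 0 at
$\Delta t = 0$, and $-c_d e^{\Delta t/\tau_d}$ for $\Delta t < 0$, applied
to the *delay-corrected* timing difference
$t_{post} - t_{pre} - t_{delay}$, so a presynaptic spike whose effect
arrives exactly with the postsynaptic spike causes no change. Pairing is
additive and all-to-all within a finite window of $7\max(\tau_p,\tau_d)$ =
140 ms, where the kernel has decayed below $10^{-3}$ of its peak; this is
the standard additive reading, and the buffered implementation is verified
against a brute-force enumeration of every spike pair on scripted rasters.

Three constraints act on the weights: a floor at zero after every update; a
growth ceiling at `ceiling_factor` times the block's maximum starting
weight; and multiplicative normalization $W_{ji} \leftarrow W_{ji} /
\sum_i W_{ji}$, fired as one Bernoulli(0.01) event per step for all layers
jointly. The per-step order is integrate → spike → STDP → ceiling →
(possibly) normalize, and the ceiling is treated as a standing constraint —
re-applied after normalization events too — because it is stated as an
absolute bound on weight growth. Velocity-tuned subpopulations are gated
all-or-none: only the population matching the stimulus velocity is active
and plastic, so each velocity is trained independently. The zero-velocity
(static) population is never trained: with a balanced kernel and
non-directional input the expected drift is zero (verified as a property
test), so training would only reproduce the initial symmetric state.

Training per velocity runs `n_runs` independent simulations (random motion
start positions, independent Poisson noise and initial jitter) on a
*shared* connectivity graph, and averages the final weight tensors
element-wise. Sharing the graph is what makes element-wise averaging
well defined; redrawing it per run would average weights of different
edges. The learning rate ramps linearly from 0 to `lr_max` over the first
quarter of training and stays flat afterwards.

## Measurement protocols

**Activation-delay calibration.** Each layer's response to a brief flash
peaks later than the earliest possible arrival $(l-1)\,t_{delay}$ of
stimulus information, because the leaky membrane needs time to build up a
response. `compute_activation_delays()` runs a deterministic rate-only
version of the network (expected input instead of sampled spikes) with a
20 ms flash, on untrained weights, and records the peak time of the single
neuron best tuned to the flash position in each layer. The resulting
per-layer comparison timepoints (earliest arrival + activation delay) are
used by all spiking comparisons; the calibration is deterministic and
bitwise reproducible.

**Spike collection.** For each trial a motion stimulus runs 700 ms through
the trained network; at the trial midpoint a 20 ms flash is presented at
the motion stimulus's current location as separate input to the static
network. At each layer's comparison timepoint the circular difference
between the two networks' population spiking peaks is recorded, signed
positive along the motion direction. The input layer is the built-in
consistency check: its flash and motion responses are compared at the
stimulus-aligned moment, so its mean difference must converge to zero.

**Realtime lag.** Independently of the flash probe, each layer's spiking
peak at the trial midpoint is compared with the true concurrent stimulus
position (all layers at the same timepoint). The *alignment score* is the
mean absolute circular deviation of the layer-2..$N_l$ mean representations
from the input layer's; 0 means all layers agree.

Population peaks are estimated by pooling a layer's spikes in a symmetric
±5 ms window around the evaluation timepoint, smoothing the spike positions
with a wrapped-Gaussian kernel, and taking the grid argmax. The window is
symmetric so it biases neither the moving nor the stationary response; a
trial in which a layer is silent inside its window is excluded for that
layer and counted (with default rates this does not occur in practice).
Angular errors are averaged across trials by maximum-likelihood von Mises
fits (circular mean plus Newton-refined concentration from the mean
resultant length).

## Numerical choices

- **Ring geometry.** All positions live on $[0,1)$; signed distances are
  wrapped to $[-0.5, 0.5)$, with the antipodal tie mapped to $-0.5$. All
  Gaussians (connectivity, stimulus, smoothing kernels) are wrapped by
  3-term image sums, which is exact to machine precision for widths up to
  about 1/8 cycle because distances are pre-wrapped.
- **KDE bandwidth.** No canonical bandwidth exists for the spike-position
  density, so the package defaults to $\sigma_p$ (= 1/32), the generative
  width of the input activation, exposed as `kde_sigma`.
- **Receptive-field center.** The circular mean of the smoothed weight
  profile is used as the center (robust at grid resolution); the grid peak
  is also available, and the two agree within one grid step for unimodal
  near-symmetric profiles (tested).
- **Ties and degeneracies.** Grid argmax ties break at the smallest index;
  the von Mises concentration is capped at $10^4$ for all-equal samples,
  and a vanishing resultant leaves the mean direction flagged undefined.
- **Warm-up.** Delay buffers and higher-layer rates are warmed up with
  $2 N_l t_{delay}$ of baseline activity before any measurement, so onset
  transients do not contaminate statistics.
- **Determinism.** All randomness flows from one master seed through a
  fixed integer seed-stream derivation (`seed_stream()`); the engine draws
  from R's RNG, so any stage is reproducible under `set.seed()`.
- **Performance.** The per-step loop is compiled (Rcpp), with spike-index
  histories and per-neuron edge indexing so plasticity work scales with the
  number of spikes rather than the number of synapses.

## What the generator emulates — and what it does not

All inputs are synthetic by design: moving point stimuli and stationary
flashes on a ring, encoded as inhomogeneous Poisson spiking. This captures
the timing structure that drives STDP (ordered activation of neighbouring
receptive fields, delayed feedforward conduction, integration lag) but
deliberately omits most of real early vision: two-dimensional space,
stimuli with extended contours or multiple motion components, velocity
tuning *formation* (populations are assumed pre-tuned and gated
all-or-none), conductance-based membrane dynamics, and any feedback or
horizontal connectivity. Passing tests therefore demonstrate properties of
this idealized circuit, not of biological vision.

## Desk-scale conditions used by the test suite

The default scale (2000 neurons × 6 layers, 14 velocities × 10 runs) is a
multi-hour computation. The test suite uses reduced sizes chosen once:
unit and property tests run tiny networks (40–400 neurons, 2–6 layers);
the trend tests run 400-neuron networks with every temporal parameter at
its default value. Because the per-step receptive-field drift scales with
the presynaptic spike count (proportional to layer width), the reduced
networks are trained for $2000/400 = 5$ times the default number of steps
(100000, ramp kept at one quarter) so they are measured in the equivalent
asymptotic state; this scaling reproduces the full-scale velocity trends
(e.g. the layer-2 shift peak near 1 cycle/s) at a fraction of the cost.
Trial counts for the stochastic protocols are 30–50 per experiment, with
von Mises standard errors used in the assertions.

## Known limitations

- **Slow approach to the weight asymptote.** Under these equations the
  receptive-field shift keeps growing slowly at the end of a default-length
  training run (the growth decelerates — each quarter adds less than the
  one before — but the final quarter still adds roughly a fifth of the
  total at full scale). Analyses that assume a fully saturated weight state
  should train longer; the trend tests do (see above).
- **Weak over-extrapolation at low velocities.** At the lowest velocities
  the trained shift only marginally exceeds the $v \times$ delay needed for
  compensation, so realtime representations end up near-balanced rather
  than strongly ahead of the stimulus. As a consequence the cross-layer
  alignment score is near-minimal at *both* ends of the 0.1–1.0 cycles/s
  range (best around 0.1 and 1.0, worst near 0.4–0.5), rather than having
  a unique interior minimum; the acceptance suite documents this as an
  open discrepancy rather than papering over it.
- The one-dimensional ring with a single fixed delay per hop cannot probe
  delay-line selection or two-dimensional motion; these are out of scope.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes the package's structural acceptance
quantities from scratch against the installed package (normalization
conservation and the training-time growth-ceiling bound) and writes them as
JSON; see the README for invocation.
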