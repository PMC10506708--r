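# stdpnet

Simulation and analysis of motion extrapolation by spike-timing dependent
plasticity (STDP) in a multi-layer feedforward spiking network.

## The problem

Neural conduction delays (about 20 ms per processing stage) and membrane
integration mean that deeper levels of a visual hierarchy work on
progressively outdated input. For a moving stimulus this creates
*representational lag*: the position encoded by a population of neurons
trails the stimulus's true position, by more at deeper layers and higher
speeds. `stdpnet` is for computational neuroscientists studying a proposed
compensation mechanism: STDP acting purely along the feedforward pathway of
velocity-tuned neurons.

## The model

Each of $N_l = 6$ layers holds $N_n = 2000$ Poisson-spiking neurons tuned to
positions on the ring $[0,1)$. A point stimulus drives the input layer with
a wrapped-Gaussian rate bump (peak $r_b + 20 r_b = 105$ Hz, width
$\sigma_p = 1/32$); higher layers integrate delayed spikes through sparse
feedforward weights $W$:

$$r_j^l(t) = r_j^l(t{-}\Delta t)\,e^{-\Delta t/\tau_m}
 + \tfrac{\Delta t}{\tau_m}\, I_j^l(t),\qquad
 I_j^l(t) = \tfrac{1}{\Delta t}\textstyle\sum_i W_{ji} S_i^{l-1}(t - t_{delay}).$$

During training, weights evolve under balanced additive STDP,
$\Delta w_{ji} = p_t\, F(t_j - t_i - t_{delay})$ with
$F(\Delta t) = \pm e^{-|\Delta t|/20\,\mathrm{ms}}$, a hard floor at zero, a
growth ceiling at 3× the maximum starting weight, and stochastic
multiplicative normalization of each neuron's incoming sum to 1. Because
presynaptic cells on the approaching side of a receptive field fire before
the postsynaptic cell and cells on the leaving side after it, STDP shifts
receptive fields *opposite* to motion — which shifts the population-encoded
position *forward*, against the lag. The package implements the network and
plasticity engine (compiled core), the measurement protocols
(activation-delay calibration, motion-vs-flash spike collection, realtime
lag), and circular statistics (wrapped-Gaussian KDE, von Mises fitting,
receptive-field shift, cross-layer alignment).

## Worked example

A desk-scale run (400 neurons, 4 layers, all temporal parameters at their
defaults; ~1 minute):

```r
library(stdpnet)
set.seed(1)
cfg <- reduced_profile(network_config(), n_neurons = 400, n_layers = 4,
                       n_train_steps = 40000, n_runs = 2)
graph     <- build_connectivity(cfg)
untrained <- init_weights(graph, cfg)
trained   <- train_subpopulation(cfg, velocity = 0.5, graph = graph)

for (l in 2:4)
  cat(sprintf("layer %d receptive-field shift: %+.4f cycles\n", l,
              measure_rf_shift(trained, untrained, l)))

lag_tr <- realtime_lag_experiment(trained,   0.5, cfg, n_trials = 30)
lag_un <- realtime_lag_experiment(untrained, 0.5, cfg, n_trials = 30)
cat(sprintf("alignment score: trained %.4f, untrained %.4f\n",
            realtime_alignment(lag_tr$table), realtime_alignment(lag_un$table)))
```

Output:

```
layer 2 receptive-field shift: +0.0152 cycles
layer 3 receptive-field shift: +0.0094 cycles
layer 4 receptive-field shift: +0.0064 cycles
alignment score: trained 0.0056, untrained 0.0330
```

Reading it: after training on 0.5 cycles/s motion, layer-2 receptive fields
have shifted 0.015 cycles opposite to motion (positive sign = opposite to
motion), with smaller inherited shifts above. In the untrained network the
realtime representation lags the stimulus by up to 0.053 cycles at layer 4;
training pulls every layer back toward the stimulus position, improving the
cross-layer alignment score from 0.033 to 0.006 cycles (0 = all layers
represent the same position as the input layer). `velocity_sweep()`
orchestrates these measurements over a velocity × membrane-time-constant
grid into one tidy table, and `inst/scripts/stdpnet-cli.R` exposes the same
stages as shell subcommands (`train`, `calibrate-delays`, `collect-spikes`,
`realtime-lag`, `sweep`).

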