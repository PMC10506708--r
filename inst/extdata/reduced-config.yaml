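# Desk-scale configuration: sizes cut down, every temporal parameter at its
# reference value. Absent keys take the package defaults.
n_neurons: 400
n_layers: 4
n_train_steps: 40000
ramp_steps: 10000
n_runs: 2
velocities: [0.2, 0.4, 0.6, 0.8, 1.0]
seed: 1
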