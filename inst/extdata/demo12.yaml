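# Desk-scale demo: 12-node roster (2 nodes per system), planted halving
# of DMN module switching between the two conditions.
nodes_per_system: 2
n_trials: 50
fs: 500
trial_duration: 2
band: [8, 13]
noise_sd: 0.3
coupling: 1
n_modules: 2
switch_prob: 0.4
effect:
  switch_mult:
    DMN: 0.5
window_ms: 300
overlap: 0.5
gamma: 1
omega: 0.25
reps: 50
alpha: 0.05
seed: 42
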