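# Example pipeline configuration (synthetic run).
out_dir: netswitch_out
seed: 7
simulate:
  n_per_group: {dependent: 4, control: 4}
  events_lambda: 3
  effect: 0.5
window: {width: 40, step: 10, trim_initial: 10}
multilayer: {gamma: 1.0, omega: 1.0, n_repetitions: 5}
stats_levels: [global, subnetwork]
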