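# Desk-scale end-to-end run on the built-in core_like toy model.
toy: core_like
toy_seed: 7
substrate: EX_glc
growth: BIO
product: EX_ac
substrate_interval: [-10, -2]
n_patterns: 20
per_pattern: 5
n_default: 100
sampler:
  thinning: 20
  n_chains: 4
rel_window: 0.10
correlation_threshold: 0.95
n_orders: 50
k: 5
seed: 1
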