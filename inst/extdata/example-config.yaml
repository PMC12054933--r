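# Reference two-memory training experiment (mixed inhibition).
# Omitted fields fall back to the package defaults.
network:
  N: 100
  n_exc: 80
  n_hebb: 10
  n_anti: 10
stdp:
  M: 2          # forgetting term f = f0 / M = 0.1
  gamma_l: 0.005
  lambda: 100
protocol:
  regime: mixed
  M: 2
  mode: random
  n_epochs: 35
  rest: 5
  consolidation: 20
seed: 1
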