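# Compare both learning paradigms against the adaptive-dynamics prediction
# in the branching environment. Bare N / T keys are valid here (YAML
# booleans are mapped back to the parameter names).
environment: branching
mode: both
seeds: [1, 2, 3]
social:
  N: 200
  T: 10000
individual:
  N: 200
  T: 100000
  thin: 100
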