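# Example simulation spec for runSimulation(): a small phantom with an
# upper-lobe-predominant EI profile plus a default cohort.
phantom:
  dims: [48, 48, 48]
  spacing: [1, 1, 1]
  eiTargets: {RUL: 55, RML: 37, RLL: 32, LUL: 55, LLi: 33, LLL: 28}
  placement: mixed
  seed: 42
cohort:
  seed: 42
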