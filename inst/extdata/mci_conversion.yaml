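# Default configuration: MCI conversion task (36-month progression from
# MCI to AD).
task: mci-conversion
n_positive: 47
n_negative: 30
correlation:
  model: block
  r_in: 0.5
  r_out: 0.2
seed: 1
bookkeeping:
  unavailable: 49
  deceased: 13
  other_dementia: 3
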