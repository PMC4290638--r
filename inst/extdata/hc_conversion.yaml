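# Default configuration: healthy-control conversion task (36-month
# progression from HC to MCI or AD).
task: hc-conversion
n_positive: 31        # converters
n_negative: 604       # stayed cognitively healthy
correlation:
  model: block
  r_in: 0.5
  r_out: 0.2
seed: 1
bookkeeping:
  unavailable: 148
  deceased: 13
  other_dementia: 1
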