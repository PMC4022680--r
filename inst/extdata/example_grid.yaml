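# Example sweep configuration: groups of 10 at three Nutrition/Sociality
# ratios over the upper transfer range.
grid:
  n: [10]
  transfer: [60, 70, 80, 90, 100]
  ratio: [1.5, 1, 0.67]
engine:
  reps: 50
  max_days: 900
base_seed: 20140515
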