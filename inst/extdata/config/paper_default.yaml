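# Full-census configuration: 32 mice, 157 scans, 49 test-retest pairs on
# the reference 128 x 64 x 256 geometry, base-16 model, 120-epoch budget.
# Provided for completeness; simulation and training at this scale take
# hours on a single CPU.
cohort:
  preset: paper_default
model:
  base_filters: 16
  depth: 4
training:
  batch_size: 40
  max_epochs: 120
  learning_rate: 0.001
scenarios: [full, ts1, ts2, tsm]
threshold: 0.5
seed: 1
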