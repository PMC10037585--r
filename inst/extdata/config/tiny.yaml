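# Desk-scale configuration: 6-mouse cohort on a 64 x 32 x 128 grid,
# base-8 attention U-Net; run-all finishes on one CPU in minutes.
cohort:
  preset: tiny
model:
  base_filters: 8
  depth: 4
training:
  batch_size: 16
  max_epochs: 10
  learning_rate: 0.002
scenarios: [full]
threshold: 0.5
seed: 1
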