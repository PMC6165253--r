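# End-to-end run on the built-in simulator
seed: 42
mode: full          # full | sar7_opt2 | sar5_opt4 | sar_only | optical_only
classifier: svm     # svm | wishart
output_dir: polcropsar_out
simulate:
  size: [128, 128]
  field_grid: [8, 8]
  looks: 4
texture:
  window: 7
  bins: 32
  band: R
pca:
  sar_threshold: 0.98
  optical_threshold: 0.99
normalization:
  robust: false
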