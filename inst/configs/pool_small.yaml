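# Small mRNA-pool demonstration: 8 genes, one phase toward a linear
# target, 4-step error, tree-descent transcription from the top layers.
initial_profile: [1, 1, 1, 1, 1, 1, 1, 1]
pool_size: 8000
alpha_dec: 0.1
record_stride: 250
phases:
  - n_repeats: 20000
    targets: [1, 2, 3, 4, 5, 6, 7, 8]
    beta: 1
    error_mode: "step:4"
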