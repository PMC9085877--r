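# Flat-list control: 8 factors competing in one list with a single shared
# error; the ratios fail to approach the targets.
n_factors: 8
kind: linear
alpha_inc: 0.1
alpha_dec: 0.1
beta: 1
gamma: 0
error_mode: exact
decay_mode: scaled
n_repeats: 100000
record_stride: 1000
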