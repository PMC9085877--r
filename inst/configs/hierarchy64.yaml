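# 64 factors in a balanced hierarchical-pair architecture, linear targets
# 1..64, exact MSE. Switch error_mode to "stepwise" or "step:3" for the
# approximated-error arms.
n_factors: 64
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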