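# One learning pair: competitive amplification (beta = 1) and exact
# MSE-dependent scaled decay toward target ratio 1:2.
targets: [1, 2]
alpha_inc: 0.1
alpha_dec: 0.1
beta: 1
gamma: 0
error_mode: exact
decay_mode: scaled
n_repeats: 100000
record_stride: 1000
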