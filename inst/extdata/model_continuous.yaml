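# Model-study configuration, continuous step-rate condition.
# Flat key: value dialect understood by read_config().
duration_s: 5
dt_s: 0.05
start_price_low: 80
start_price_high: 120
alpha: 0.88
beta: 0.88
lambda: 2.25
gamma: 0.61
delta: 0.69
c: 2.1
V: 1.27
mu: 2.01
sigma: 0.97
softmax_sign: corrected
value_anchor: start_price
condition: continuous
n_auctions: 1000
seed: 1
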