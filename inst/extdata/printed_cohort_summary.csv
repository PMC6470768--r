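characteristic,faster,slower
delta_weight_zscore_median,-0.479,-1.538
birth_weight_median_kg,1.200,1.605
n_mothers,11,11
n_nonsecretor_mothers,1,4
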