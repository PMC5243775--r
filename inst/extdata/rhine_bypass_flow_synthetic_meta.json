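{"pool_spacings_m":[1.6,1.8,2,1.7,1.6,1.8,2,1.7,1.6,1.8,2,1.7,1.6,1.8,2,1.7,4.54,1.8,2,1.7,1.6,1.8,2,1.7,1.6,1.8,2,1.7,1.6,1.8,2,1.7,1.6],"slope_pct":3.75,"length_m":65}
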