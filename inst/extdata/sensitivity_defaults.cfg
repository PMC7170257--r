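# LHS/PRCC defaults: n = 200, seed = 1, +/-50% ranges
species = mouse
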