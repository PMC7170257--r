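# human dose-grid map, 5 cycles, desk scale
species = human
# grid = 4, gammaA_max = 1e-11,
# gammaB_max = 1e-6, cycles = 5
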