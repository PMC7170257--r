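# human dose-grid map, 10 cycles, 1/10 dose range
species = human
# grid = 4, gammaA_max = 1e-12,
# gammaB_max = 1e-7, cycles = 10
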