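# Variance of pairwise IBD sharing across the four crossover models
# (full siblings through second cousins, 10,000 pairs per cell).
name = ibd-variance
relationships = full-sib, cousin-1, cousin-1-removed-1, cousin-2
models = ss-intf, ss-poisson, sa-intf, sa-poisson
pairs = 10000
bootstrap = 1000
map = synthetic-genome
interference = default
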