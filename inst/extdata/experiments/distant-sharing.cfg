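# Probability of sharing any IBD segment in distant cousins, including
# all-female and all-male connecting lineages.
name = distant-sharing
relationships = cousin-3, cousin-4, cousin-5, cousin-6, cousin-6-female, cousin-6-male
models = ss-intf, sa-poisson
pairs = 10000
bootstrap = 1000
map = synthetic-genome
interference = default
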