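# Segment counts in maternal versus paternal half-siblings under
# sex-specific maps with interference (the bimodality experiment), with
# first cousins for scale.
name = halfsib-segments
relationships = half-sib-maternal, half-sib-paternal, half-sib, cousin-1
models = ss-intf
pairs = 10000
bootstrap = 1000
map = synthetic-genome
interference = default
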