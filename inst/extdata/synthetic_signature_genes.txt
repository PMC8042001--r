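# Synthetic signature gene ids matching the generator's expression matrix
# (the planted signature set; edit freely for real data).
G0001
G0002
G0003
G0004
G0005
G0006
G0007
G0008
G0009
G0010
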