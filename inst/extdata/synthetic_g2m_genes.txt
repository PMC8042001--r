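# Synthetic G2/M gene ids for the generator's expression matrix.
G0031
G0032
G0033
G0034
G0035
G0036
G0037
G0038
G0039
G0040
G0041
G0042
G0043
G0044
G0045
G0046
G0047
G0048
G0049
G0050
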