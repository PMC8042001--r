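# Synthetic S-phase gene ids for the generator's expression matrix.
G0011
G0012
G0013
G0014
G0015
G0016
G0017
G0018
G0019
G0020
G0021
G0022
G0023
G0024
G0025
G0026
G0027
G0028
G0029
G0030
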