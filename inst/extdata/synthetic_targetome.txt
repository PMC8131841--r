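G00002
G00014
G00029
G00038
G00041
G00045
G00052
G00061
G00062
G00063
G00067
G00079
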