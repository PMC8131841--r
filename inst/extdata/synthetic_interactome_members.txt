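G00005
G00006
G00008
G00009
G00013
G00019
G00025
G00034
G00037
G00051
G00054
G00057
G00066
G00077
G00078
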