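well,target,positives,total
A01,miR-323b-3p,1487,18230
A02,miR-323b-3p,1512,19044
B01,miR-98,112,17902
B02,miR-98,96,18511
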