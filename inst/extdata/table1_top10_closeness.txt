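H19
RECK
ITGB8
JAZF1
GS1-358P8.4
DOCK4
CDC42SE2
TET3
TNFAIP3
PHTF2
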