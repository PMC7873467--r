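H19
GS1-358P8.4
RP3-523K23.2
RP11-96D1.10
DLX6-AS1
AC016747.3
RP11-284N8.3
RP11-379K17.4
HOXA-AS2
RP11-54O7.1
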