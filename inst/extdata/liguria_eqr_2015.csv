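WB,EQR
Mo,0.89
Ga,0.81
Ge,0.88
PF,0.93
PM,0.66
CT,0.64
PV,0.50
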