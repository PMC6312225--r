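WB,Urb,Ind,Agr,FW,Coast,MA-LUSI-WB
Mo,1,0,2,0,0.75,5.98
Ga,1,0,0,0,0.75,4.92
Ge,3,0,1,0,1,8.11
PF,1,0,0,0,0.75,3.39
PM,1,0,0,0,0.75,3.92
CT,1,0,2,0,1,5.92
PV,1,0,3,0,1,8.13
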