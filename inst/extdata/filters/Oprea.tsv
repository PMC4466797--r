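# name	smarts
# demonstration subset of Oprea-style lead-likeness alerts
long_aliphatic_chain	[CH2][CH2][CH2][CH2][CH2][CH2][CH2]
quaternary_nitrogen	[NX4+]
phosphonium	[P+]
polyene	[CX3]=[CX3][CX3]=[CX3][CX3]=[CX3]
perhalogenated_carbon	[CX4]([F,Cl,Br])([F,Cl,Br])([F,Cl,Br])[F,Cl,Br]
crown_ether_like	[OX2][CX4][CX4][OX2][CX4][CX4][OX2]
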