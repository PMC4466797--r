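# name	smarts
# demonstration subset of Glaxo-style reactive/unsuitable-group alerts
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
aldehyde	[CX3H1]=[OX1]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
alkyl_bromide_iodide	[CX4][Br,I]
azide	N=[N+]=[N-]
peroxide	[OX2][OX2]
isocyanate	[NX2]=[CX2]=[OX1]
disulfide	[SX2][SX2]
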