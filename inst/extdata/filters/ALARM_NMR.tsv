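# name	smarts
# demonstration subset of ALARM-NMR-style thiol-reactivity alerts
maleimide	O=C1C=CC(=O)N1
quinone	O=C1C=CC(=O)C=C1
enone	[CX3]=[CX3][CX3]=[OX1]
alpha_halo_ketone	[CX3](=[OX1])[CX4][Cl,Br,I]
disulfide	[SX2][SX2]
nitroaromatic	[c][$([NX3](=O)=O),$([NX3+](=O)[O-])]
epoxide	C1OC1
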