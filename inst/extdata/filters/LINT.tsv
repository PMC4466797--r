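# name	smarts
# demonstration subset of Pfizer-LINT-style alerts
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
thioester	[SX2][CX3]=[OX1]
sulfonate_ester	[SX4](=O)(=O)[OX2][#6]
nitroso	[#6][NX2]=[OX1]
acyclic_imine	[CX3;!R]=[NX2;!R][#6]
beta_lactam	O=C1CCN1
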