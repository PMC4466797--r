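# feature	smarts
# atom-level chemical feature definitions for the pharmacophore-pair fingerprint
donor	[#7,#8;!H0]
acceptor	[$([OX1]),$([OX2]),$([nX2]),$([NX1]),$([NX2]),$([NX3;!$([NX3][CX3]=[OX1]);!$([NX3]a)])]
aromatic	[a]
hydrophobic	[$([#6;!$([#6]~[#7,#8,F,Cl,Br,I,#16]);$([#6]~[#6])]),$([SX2]([#6])[#6]),F,Cl,Br,I]
positive	[$([*+;!$([*+]~[*-])]),$([NX3;H2,H1;!$([NX3][CX3]=[OX1]);!$([NX3]a)])]
negative	[$([*-;!$([*-]~[*+])]),$([OX2H1][CX3]=[OX1]),$([OX2H1][SX4](=[OX1])=[OX1])]
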