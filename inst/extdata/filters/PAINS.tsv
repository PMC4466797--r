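# name	smarts
# demonstration subset of PAINS-style assay-interference alerts
quinone_A	O=C1C=CC(=O)C=C1
catechol	[OX2H]c1ccccc1[OX2H]
hydroquinone	[OX2H]c1ccc([OX2H])cc1
azo_aryl	c[NX2]=[NX2]c
mannich_base	[OX2H]c1ccccc1[CX4H2][NX3]
enamine_nitrile	[NX3][CX3]=[CX3][CX2]#[NX1]
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1[CX3]=[NX2][NX3]
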