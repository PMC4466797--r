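# name	smiles	counterion
# substituent fragments; empty smiles = hydrogen; counterion appended as a
# separate component when present
hydrogen		
methyl	C	
ethyl	CC	
propyl	CCC	
isopropyl	C(C)C	
hydroxyl	O	
methoxy	OC	
ethoxy	OCC	
hydroxymethyl	CO	
amino	N	
methylamino	NC	
dimethylamino	N(C)C	
fluoro	F	
chloro	Cl	
bromo	Br	
trifluoromethyl	C(F)(F)F	
nitrile	C#N	
carboxylic_acid	C(=O)O	
methyl_ester	C(=O)OC	
amide	C(=O)N	
acetamido	NC(C)=O	
acetyl	C(C)=O	
vinyl	C=C	
allyl	CC=C	
enone	C=CC(C)=O	
dienyl	C=CC=C	
nitro	[N+](=O)[O-]	
nitrate_ester	CO[N+](=O)[O-]	
carboxylate	C(=O)[O-]	[Na+]
ammonium_methyl	C[NH3+]	[Cl-]
thiol	S	
methylthio	SC	
phenyl	c9ccccc9	
benzyl	Cc9ccccc9	
sulfonamide	S(=O)(=O)N	
methanesulfonyl	S(C)(=O)=O	
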