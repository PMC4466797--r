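# fragment_id	name	smarts
# Bundled substructure-fingerprint dictionary (demonstration subset of a
# SubFP-style named-fragment dictionary). A "&&"-joined SMARTS means every
# component pattern must match somewhere in the molecule.
FR001	Alkene	[CX3]=[CX3]
FR002	Alkyne	[CX2]#[CX2]
FR003	Arene	c1ccccc1
FR004	Alcohol	[OX2H][CX4]
FR005	Phenol	[OX2H][c]
FR006	Ether	[OD2]([#6])[#6]
FR007	Aldehyde	[CX3H1]=[OX1]
FR008	Ketone	[#6][CX3](=[OX1])[#6]
FR009	Carboxylic acid	[CX3](=O)[OX2H1]
FR010	Ester	[#6][CX3](=[OX1])[OX2][#6]
FR011	Amide	[NX3][CX3]=[OX1]
FR012	Primary amine	[NX3;H2;!$(NC=O)][#6]
FR013	Secondary amine	[NX3;H1;!$(NC=O)]([#6])[#6]
FR014	Tertiary amine	[NX3;H0;!$(NC=O);!$(N=O);!$([N+])]([#6])([#6])[#6]
FR015	Nitrile	[NX1]#[CX2]
FR016	Nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
FR017	Nitrate	[$([OX2][NX3](=O)=O),$([OX2][NX3+](=O)[O-])]
FR018	Halide	[F,Cl,Br,I]
FR019	Thiol	[SX2H]
FR020	Thioether	[SX2]([#6])[#6]
FR021	Sulfonamide	[SX4](=O)(=O)[NX3]
FR022	Sulfone	[SX4](=O)(=O)([#6])[#6]
FR023	Michael acceptor	[CX3]=[CX3][CX3]=[OX1]
FR024	Vinylogous ester	[#6][OX2][CX3]=[CX3][CX3]=[OX1]
FR025	Conjugated double bond	[CX3]=[CX3][CX3]=[CX3]
FR026	Anion	[*-]
FR027	Cation	[*+]
FR028	Salt	[*+] && [*-]
FR029	Quinone	O=C1C=CC(=O)C=C1
FR030	Epoxide	C1OC1
FR031	Urea	[NX3][CX3](=[OX1])[NX3]
FR032	Carbamate	[NX3][CX3](=[OX1])[OX2][#6]
FR033	Guanidine	[NX3][CX3](=[NX2])[NX3]
FR034	Imine	[CX3]=[NX2]
FR035	Pyridine ring	c1ccncc1
FR036	Pyrrole-type NH	[nX3H1]
FR037	Furan ring	c1ccoc1
FR038	Thiophene ring	c1ccsc1
FR039	Trifluoromethyl	[CX4](F)(F)F
FR040	Aromatic halide	[c][F,Cl,Br,I]
FR041	Benzylic carbon	[CX4H2][c]
FR042	Sulfonic acid	[SX4](=O)(=O)[OX2H1]
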