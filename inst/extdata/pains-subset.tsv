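# Representative subset of the published pan-assay interference (PAINS)
# substructure catalog, expressed as SMARTS that the OpenBabel matcher
# supports. Supply a full catalog in the same format for exhaustive
# screening.
name	family	smarts
quinone_para	A	[#6]1(=O)[#6]=[#6][#6](=O)[#6]=[#6]1
quinone_ortho	A	O=[#6]1[#6](=O)[#6]=[#6][#6]=[#6]1
quinone_methide	A	[#6]=[#6]1[#6]=[#6][#6](=O)[#6]=[#6]1
catechol	A	[OX2H]c1ccccc1[OX2H]
hydroquinone	B	[OX2H]c1ccc([OX2H])cc1
rhodanine	A	S=C1NC(=O)CS1
ene_rhodanine	A	S=C1NC(=O)C(=[#6])S1
thiazolidinone_ene	A	O=C1NC(=S)SC1=[#6]
hydroxyphenyl_hydrazone	A	[OX2H]c1ccccc1[#6]=[#7][#7]
phenol_schiff	B	[OX2H]c1ccccc1[#6]=[#7][#6]
azo_aryl	A	c[#7]=[#7]c
alkylidene_barbiturate	A	O=C1NC(=O)NC(=O)C1=[#6]
alkylidene_oxindole	B	O=C1Nc2ccccc2C1=[#6]
ene_one_ene	A	[#6]=[#6]C(=O)[#6]=[#6]
anil_di_alk	B	c1ccc(cc1)N(C)C
thiophene_amino	B	c1cc(sc1)[NX3H2]
aminothiazole_enone	B	[#6]=[#6]c1nc(N)sc1
maleimide	B	O=C1C=CC(=O)N1
isothiazolone	A	O=C1C=CSN1
nitroso	A	[#6][NX2]=O
diazonium	A	[#6][N+]#N
acyl_hydrazide_ene	B	[#6]=[#6]C(=O)NN
beta_keto_anhydride	B	O=C1OC(=O)C(=C1)[#6]
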