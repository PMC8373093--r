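dr	Debus-Radziszewski imidazole synthesis	[C:1](=O)[C:2]=O.[CH1:3]=O>>[c:1]1[c:2][nH][c:3]n1	O=C(c1ccccc1Cl)C(=O)c1ccccc1Cl.C=CCc1cccc(C=O)c1O	C=CCc1cccc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)c1O	1,2-diketone + aldehyde + implicit ammonia source (NH4OAc/AcOH)
ester	O-acylation of phenols	[C:1](=[O:2])[OH1].[OH1:3][c:4]>>[C:1](=[O:2])[O:3][c:4]	CC(=O)O.Oc1ccccc1	CC(=O)Oc1ccccc1	Steglich DCC/DMAP esterification; acyl-halide variant equivalent
amide	Amide coupling	[C:1](=[O:2])[OH1].[NH2:3][C:4]>>[C:1](=[O:2])[NH1:3][C:4]	CC(=O)O.NCC	CCNC(C)=O	carbodiimide-mediated amide bond formation
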