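# template, published de novo designs, intermediate, building blocks, acids
Oc1ccccc1C(=O)c1cc(Cl)c(Cl)n1-c1c(Cl)c(Cl)[nH]c1C(=O)c1ccccc1O	marinopyrrole_A
C=CCc1cccc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)c1OC(=O)CO	design_2
C=CCc1cccc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)c1OC(=O)COC	design_2a
C=CCc1cccc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)c1OC(=O)C	design_2b
CCOc1cc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)ccc1O	design_3
C=CCc1cccc(-c2nc(-c3ccccc3Cl)c(-c4ccccc4Cl)[nH]2)c1O	intermediate_4
O=C(c1ccccc1Cl)C(=O)c1ccccc1Cl	block_5_diketone
C=CCc1cccc(C=O)c1O	block_6_aldehyde
CCOc1cc(C=O)ccc1O	block_7_aldehyde
OCC(=O)O	glycolic_acid
COCC(=O)O	methoxyacetic_acid
CC(=O)O	acetic_acid
c1ccc(-c2nc(-c3ccccc3)c(-c4ccccc4)[nH]2)cc1	lophine
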