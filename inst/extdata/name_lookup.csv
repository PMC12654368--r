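name,smiles
2-phenylethyl acetate,CC(=O)OCCc1ccccc1
acetic acid 2-phenylethyl ester,CC(=O)OCCc1ccccc1
"acetic acid, 2-phenylethyl ester",CC(=O)OCCc1ccccc1
phenethyl acetate,CC(=O)OCCc1ccccc1
menthyl acetate,CC(=O)O[C@@H]1C[C@@H](C)CC[C@H]1C(C)C
2-pentylfuran,CCCCCc1ccco1
furfural,O=Cc1ccco1
citronellol,CC(CCCC(C)=CC)CO
beta-citronellol,OCCC(C)CCC=C(C)C
nerol,CC(C)=CCC/C(C)=C\CO
cis-geraniol,CC(C)=CCC/C(C)=C\CO
geraniol,CC(C)=CCC/C(C)=C/CO
"butanoic acid, 2-methylbutyl ester",CCCC(=O)OCC(C)CC
butanoic acid 2-methylbutyl ester,CCCC(=O)OCC(C)CC
phenethyl alcohol,OCCc1ccccc1
2-phenylethanol,OCCc1ccccc1
hexanal,CCCCCC=O
ethanol,CCO
linalool,CC(C)=CCCC(C)(O)C=C
limonene,CC(=C)C1CCC(C)=CC1
benzaldehyde,O=Cc1ccccc1
ethyl acetate,CCOC(C)=O
ethyl butanoate,CCCC(=O)OCC
isoamyl acetate,CC(C)CCOC(C)=O
vanillin,COc1cc(C=O)ccc1O
eugenol,C=CCc1ccc(O)c(OC)c1
menthol,CC(C)[C@@H]1CC[C@@H](C)C[C@H]1O
acetic acid,CC(=O)O
butanoic acid,CCCC(=O)O
hexanol,CCCCCCO
1-hexanol,CCCCCCO
toluene,Cc1ccccc1
benzyl alcohol,OCc1ccccc1
benzyl acetate,CC(=O)OCc1ccccc1
gamma-decalactone,CCCCCCC1CCC(=O)O1
diacetyl,CC(=O)C(C)=O
2-heptanone,CCCCCC(C)=O
methional,CSCCC=O
dimethyl sulfide,CSC
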