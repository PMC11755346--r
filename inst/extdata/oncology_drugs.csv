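drug_id,smiles
Cisplatin,N.N.Cl[Pt]Cl
Carboplatin,N.N.O=C1O[Pt]OC(=O)C12CCC2
Oxaliplatin,O=C1O[Pt]2(OC1=O)N[C@@H]1CCCC[C@H]1N2
Fluorouracil,O=c1[nH]cc(F)c(=O)[nH]1
Capecitabine,CCCCCOC(=O)Nc1nc(=O)n(cc1F)[C@H]1O[C@@H](C)[C@H](O)[C@@H]1O
Gemcitabine,NC1=NC(=O)N([C@H]2O[C@@H](CO)[C@H](O)C2(F)F)C=C1
Temozolomide,Cn1nnc2c(C(N)=O)ncn2c1=O
Paclitaxel,CC1=C2[C@@]([C@]([C@H]([C@@H]3[C@]4([C@H](OC4)C[C@@H]([C@]3(C(=O)[C@@H]2OC(=O)C)C)O)OC(=O)C)OC(=O)c5ccccc5)(C[C@@H]1OC(=O)[C@H](O)[C@@H](NC(=O)c6ccccc6)c7ccccc7)O)(C)C
Docetaxel,CC1=C2[C@@]([C@]([C@H]([C@@H]3[C@]4([C@H](OC4)C[C@@H]([C@]3(C(=O)[C@@H]2OC(=O)C)C)O)O)OC(=O)c5ccccc5)(C[C@@H]1OC(=O)[C@H](O)[C@@H](NC(=O)OC(C)(C)C)c6ccccc6)O)(C)C
Doxorubicin,C[C@H]1[C@H]([C@H](C[C@@H](O1)O[C@H]2C[C@@](Cc3c2c(c4c(c3O)C(=O)c5cccc(c5C4=O)OC)O)(C(=O)CO)O)N)O
Etoposide,CC1OCC2C(O1)C(C(C(O2)OC3c4cc5c(cc4C(C6C3C(=O)OC6)c7cc(c(c(c7)OC)O)OC)OCO5)O)O
Tamoxifen,CC/C(=C(\c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1
Bicalutamide,CC(O)(CS(=O)(=O)c1ccc(F)cc1)C(=O)Nc1ccc(C#N)c(C(F)(F)F)c1
Erlotinib,COCCOc1cc2ncnc(Nc3cccc(C#C)c3)c2cc1OCCOC
Gefitinib,COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1
Dasatinib,Cc1nc(Nc2ncc(C(=O)Nc3c(C)cccc3Cl)s2)cc(N2CCN(CCO)CC2)n1
Pazopanib,CN(c1ccc2c(C)n(C)nc2c1)c1ccnc(Nc2ccc(C)c(S(N)(=O)=O)c2)n1
Sorafenib,CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1
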