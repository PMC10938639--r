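"name","smiles","primary_class","secondary_class"
"PFBA","OC(=O)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFCAs"
"PFHxA","OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFCAs"
"PFOA","OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFCAs"
"PFNA","OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFCAs"
"PFBS","OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFSAs"
"PFHxS","OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFSAs"
"PFOS","OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PFAAs","PFSAs"
"6:2 FTOH","OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Fluorotelomer_PFAA_precursors","FTOHs"
"8:2 FTOH","OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Fluorotelomer_PFAA_precursors","FTOHs"
"6:2 FTAC","C=CC(=O)OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Fluorotelomer_PFAA_precursors","n2_FTACs"
"8:2 FTMAC","C=C(C)C(=O)OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Fluorotelomer_PFAA_precursors","n2_FTACs"
"FOSA","NS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","FASA_based_PFAA_precursors","FASAs"
"N-MeFOSA","CNS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","FASA_based_PFAA_precursors","N_Alkyl_FASAs"
"N-EtFOSE","OCCN(CC)S(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","FASA_based_PFAA_precursors","FASEs"
"N-MeFOSAA","OC(=O)CN(C)S(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","FASA_based_PFAA_precursors","N_Alkyl_FASACs"
"POSF","FS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PASF_based_substances","PASFs"
"PBSF","FS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","PASF_based_substances","PASFs"
"perfluorohexylbenzene","FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)c1ccccc1","Side_chain_aromatics","Others"
"2-perfluorobutyl-bithiophene","FC(F)(F)C(F)(F)C(F)(F)C(F)(F)c1ccc(-c2cccs2)s1","Side_chain_aromatics","Others"
"perfluorohexane","FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Other_aliphatics","Others"
"perfluoro(methyl butyl) ether","FC(F)(F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)F","Other_aliphatics","PFPEs"
"1H,4H-perfluorobutane","C(F)(F)C(F)(F)C(F)(F)C(F)(F)","Other_aliphatics","Others"
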