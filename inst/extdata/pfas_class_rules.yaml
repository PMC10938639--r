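# Builtin PFAS classification rules.
#
# Ordered substructure hierarchy: the first rule (lowest priority number)
# whose every `all_of` pattern matches (and no `none_of` pattern matches)
# assigns the primary and secondary class. Aromatic-core rules come first so
# a perfluoroalkyl chain on an aromatic system always classifies as a
# side-chain aromatic, even when an acid head is present; the catch-all
# guarantees every PFAS receives a class.
rules:
  - rule_id: side_chain_aromatic
    priority: 10
    primary: Side_chain_aromatics
    secondary: Others
    all_of: ["a", "[CX4](F)F"]
  - rule_id: pfsa
    priority: 20
    primary: PFAAs
    secondary: PFSAs
    all_of: ["[CX4](F)(F)S(=O)(=O)[OX2H1,OX1-]"]
  - rule_id: pfca
    priority: 30
    primary: PFAAs
    secondary: PFCAs
    all_of: ["[CX4](F)(F)C(=O)[OX2H1,OX1-]"]
  - rule_id: n_alkyl_fasac
    priority: 40
    primary: FASA_based_PFAA_precursors
    secondary: N_Alkyl_FASACs
    all_of: ["[CX4](F)(F)S(=O)(=O)[NX3][CH2]C(=O)[OX2H1,OX1-]"]
  - rule_id: fase
    priority: 50
    primary: FASA_based_PFAA_precursors
    secondary: FASEs
    all_of: ["[CX4](F)(F)S(=O)(=O)[NX3][CH2][CH2][OX2H]"]
  - rule_id: n_alkyl_fasa
    priority: 55
    primary: FASA_based_PFAA_precursors
    secondary: N_Alkyl_FASAs
    all_of: ["[CX4](F)(F)S(=O)(=O)[NX3][CX4]"]
  - rule_id: fasa
    priority: 60
    primary: FASA_based_PFAA_precursors
    secondary: FASAs
    all_of: ["[CX4](F)(F)S(=O)(=O)[NX3]"]
  - rule_id: n2_ftac
    priority: 70
    primary: Fluorotelomer_PFAA_precursors
    secondary: n2_FTACs
    all_of: ["[CX4](F)(F)[CH2][CH2]OC(=O)C=C"]
  - rule_id: ftoh
    priority: 80
    primary: Fluorotelomer_PFAA_precursors
    secondary: FTOHs
    all_of: ["[CX4](F)(F)[CH2][CH2][OX2H]"]
  - rule_id: fluorotelomer_other
    priority: 90
    primary: Fluorotelomer_PFAA_precursors
    secondary: Others
    all_of: ["[CX4](F)(F)[CH2][CH2]"]
  - rule_id: pasf
    priority: 100
    primary: PASF_based_substances
    secondary: PASFs
    all_of: ["[CX4](F)(F)S(=O)(=O)F"]
  - rule_id: perfluoroether
    priority: 900
    primary: Other_aliphatics
    secondary: PFPEs
    all_of: ["[CX4](F)(F)O[CX4](F)F"]
  - rule_id: other_pfas
    priority: 1000
    primary: Other_aliphatics
    secondary: Others
    all_of: []
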