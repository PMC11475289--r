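# Default reactive-group and exclusion substructure rules.
# Reactive groups are routed through the functional-transformation conversion
# step; exclusions remove a compound outright. Supply curated corporate lists
# via load_filter_rules() for production use.
reactive:
  - name: acyl_halide
    smarts: "[CX3](=O)[F,Cl,Br,I]"
  - name: sulfonyl_halide
    smarts: "[SX4](=O)(=O)[F,Cl,Br,I]"
  - name: aldehyde
    smarts: "[CX3H1](=O)[#6]"
  - name: michael_acceptor
    smarts: "[CX3]=[CX3][CX3]=[OX1]"
  - name: benzylic_halide
    smarts: "[CH2X4]([F,Cl,Br,I])c"
  - name: epoxide
    smarts: "C1OC1"
  - name: aziridine
    smarts: "C1NC1"
  - name: anhydride
    smarts: "[CX3](=O)O[CX3](=O)"
  - name: isocyanate
    smarts: "[NX2]=[CX2]=[OX1]"
exclusions:
  - name: nitro
    smarts: "[NX3](=O)=O"
  - name: nitro_charged
    smarts: "[NX3+](=O)[O-]"
  - name: n_nitroso
    smarts: "[NX3][NX2]=[OX1]"
  - name: azo
    smarts: "[#6][NX2]=[NX2][#6]"
  - name: thiourea
    smarts: "[NX3][CX3](=[SX1])[NX3]"
  - name: phosphonate_ester
    smarts: "[PX4](=O)(O[#6])O[#6]"
lipinski_max_violations: 1
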