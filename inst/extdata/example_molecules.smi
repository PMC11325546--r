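CC(=O)O acetic_acid
c1ccncc1 pyridine
Nc1ccc(cc1)C(=O)O PABA
Oc1ccc(Cl)cc1 4-chlorophenol
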