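# Ionizable-group pattern set (SMARTS subset; see ?compile_smarts).
# One pattern per line:  SMARTS  reaction  class
# Convention: the FIRST atom of each pattern is the reaction-site atom
# (the H-bearing atom for acidic patterns, the proton acceptor for basic).
# Order matters: when several patterns hit the same atom, the first line
# wins and supplies the group class.

# --- acidic groups (deprotonation sites) -----------------------------------
[OX2H1][CX3]=[OX1]              acidic  carboxylic_acid
[OX2H1][SX4](=[OX1])=[OX1]      acidic  sulfonic_acid
[OX2H1][SX3]=[OX1]              acidic  sulfinic_acid
[OX2H1][PX4]=[OX1]              acidic  phosphonic_acid
[SX2H1][CX3]=[OX1]              acidic  thioacid
[OX2H1]c                        acidic  phenol
[SX2H1]c                        acidic  thiophenol
[SX2H1][CX4]                    acidic  thiol
[SX2H1]                         acidic  thiol
[NX3H1]([CX3]=[OX1])[CX3]=[OX1] acidic  imide
[NX3H1][SX4](=[OX1])=[OX1]      acidic  sulfonamide
[NX3H2][SX4](=[OX1])=[OX1]      acidic  sulfonamide
[nX3H1]                         acidic  azole_nh
[OX2H1][NX2]=[CX3]              acidic  oxime
[OX2H1]n                        acidic  n_hydroxy_azole
[OX2H1][CX3]=[CX3]              acidic  enol
[OX2H1][CX3]=[NX2]              acidic  imidic_oh

# --- basic groups (protonation sites) --------------------------------------
[NX2]=[CX3]([NX3])[NX3]         basic   guanidine
[NX2]=[CX3][NX3]                basic   amidine
[nX2]                           basic   azine_n
[NX3H2][CX4]                    basic   amine_primary
[NX3H1]([CX4])[CX4]             basic   amine_secondary
[NX3]([CX4])([CX4])[CX4]        basic   amine_tertiary
[NX3H2]c                        basic   aniline
[NX3H1](c)[CX4]                 basic   n_alkyl_aniline
[NX3H1](c)c                     basic   diarylamine
[NX3H2][NX3]                    basic   hydrazine
[NX2]=[CX3]                     basic   imine
[NX3H2][CX3]=[CX3]              basic   enamine
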