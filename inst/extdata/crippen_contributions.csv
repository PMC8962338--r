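# Atomic contribution table for hydrophobicity (hyd, Ghose-Crippen-style
# atomic logP increments) and molar refractivity (mr, cm^3/mol), version 1.
# Types are assigned by the package's reduced atom-typing rules (see
# crippen_type()); hydrogen contributions are folded into the heavy atom that
# carries them (h_on_c / h_on_het rows).
type,hyd,mr,description
C_sp3_ps,0.1441,2.503,aliphatic sp3 C (primary/secondary) bonded only to C/H
C_sp3_tq,0.0000,2.433,aliphatic sp3 C (tertiary/quaternary) bonded only to C/H
C_sp3_ps_x,-0.2035,2.753,aliphatic sp3 C (primary/secondary) with heteroatom neighbor
C_sp3_tq_x,-0.2051,2.731,aliphatic sp3 C (tertiary/quaternary) with heteroatom neighbor
C_sp2_c,0.1551,3.513,aliphatic sp2 C double-bonded to carbon
C_sp2_x,-0.2783,5.007,aliphatic C double-bonded to a heteroatom (carbonyl-like)
C_sp,0.1333,3.904,sp carbon (triple or cumulated double bonds)
C_ar_h,0.1581,3.350,aromatic C-H
C_ar_c,0.1360,3.509,aromatic C with aliphatic carbon substituent
C_ar_ar,0.2955,4.251,aromatic C bonded to another ring system (fusion/biaryl)
C_ar_x,0.0255,3.509,aromatic C with heteroatom or halogen substituent
N_prim,-1.0190,2.262,aliphatic primary amine N
N_sec,-0.7096,2.173,aliphatic secondary amine N
N_tert,-1.0270,2.261,aliphatic tertiary amine N
N_amide,-0.5188,2.140,amide/imide N (bonded to carbonyl C)
N_ar,-0.3239,2.202,aromatic n
N_sp2,-0.3396,2.754,imine-type =N-
N_sp,-0.5660,2.982,nitrile N
N_nitro,0.0800,2.200,nitro-group N
N_plus,-1.1190,2.200,charged nitrogen
O_oh,-0.2893,0.824,hydroxyl O
O_ether,-0.0684,1.085,ether/ester sp3 O
O_dbl,-0.2500,1.800,double-bonded O (carbonyl/sulfoxide/nitro)
O_ar,0.1552,1.080,aromatic o
O_minus,-1.3260,1.200,anionic O (carboxylate/phenolate)
S_any,0.6482,7.591,sulfide/thiol S
S_ar,0.6237,7.365,aromatic s
S_ox,-0.0024,7.365,oxidized S (sulfoxide/sulfone)
P_any,0.8612,6.920,phosphorus
F_any,0.4202,0.897,fluorine
Cl_any,0.6895,5.853,chlorine
Br_any,0.8456,8.927,bromine
I_any,0.8857,14.020,iodine
Se_any,0.7000,11.000,selenium (package estimate)
B_any,-0.0320,3.000,boron (package estimate)
h_on_c,0.1230,1.057,hydrogen on carbon (folded into the heavy atom)
h_on_het,-0.2677,1.395,hydrogen on N/O/S/P/Se (folded into the heavy atom)
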