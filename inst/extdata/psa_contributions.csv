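# Topological polar-surface-area fragment increments (angstrom^2), version 1,
# Ertl-type scheme mapped to single atoms by the package's typing rules
# (see psa_type()). Atoms with no matching polar type contribute 0.
type,psa
N_3single,3.24
N_dbl,12.36
N_triple,23.79
N_h_single,12.03
N_h2,26.02
N_ar,12.89
N_ar_h,15.79
N_nitro,11.68
N_plus,0.00
N_plus_h,4.44
N_plus_h2,16.61
N_plus_h3,27.64
O_single,9.23
O_h,20.23
O_dbl,17.07
O_ar,13.14
O_minus,23.06
S_single,25.30
S_dbl,32.09
S_ar,28.24
S_sulfoxide,19.21
S_sulfone,8.38
P_3single,13.59
P_oxide,9.81
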