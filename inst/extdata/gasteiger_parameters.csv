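# PEOE (partial equalization of orbital electronegativities) parameters,
# version 1. chi(q) = a + b*q + c*q^2; chi_plus = a + b + c (cation cap;
# hydrogen uses 20.02). Keys are element_hybridization.
# P and Se triples are package estimates (documented in the vignette).
key,a,b,c
H_s,7.17,6.24,-0.56
C_sp3,7.98,9.18,1.88
C_sp2,8.79,9.32,1.51
C_sp,10.39,9.45,0.73
N_sp3,11.54,10.82,1.36
N_sp2,12.87,11.15,0.85
N_sp,15.68,11.70,-0.27
O_sp3,14.18,12.92,1.39
O_sp2,17.07,13.79,0.47
F_sp3,14.66,13.85,2.31
Cl_sp3,11.00,9.69,1.35
Br_sp3,10.08,8.47,1.16
I_sp3,9.90,7.96,0.96
S_sp3,10.14,9.13,1.38
S_sp2,10.14,9.13,1.38
P_sp3,8.90,9.10,1.38
Se_sp3,10.14,9.13,1.38
Se_sp2,10.14,9.13,1.38
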