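# Elemental property table, version 1.
# weight: IUPAC 2021 standard atomic weights (conventional values).
# en_pauling: Pauling electronegativities.
# polarizability: static dipole polarizabilities, angstrom^3.
# covalent_radius: single-bond covalent radii, angstrom (0.772 for sp3 carbon
#   is the reference value used by the Kupchik vertex degree).
# valence_electrons: electrons in the valence shell (Zv).
symbol,atomic_number,weight,en_pauling,polarizability,covalent_radius,valence_electrons
H,1,1.008,2.20,0.667,0.32,1
B,5,10.81,2.04,3.03,0.81,3
C,6,12.011,2.55,1.76,0.772,4
N,7,14.007,3.04,1.10,0.70,5
O,8,15.999,3.44,0.802,0.66,6
F,9,18.998,3.98,0.557,0.64,7
Na,11,22.990,0.93,24.11,1.54,1
Si,14,28.085,1.90,5.38,1.17,4
P,15,30.974,2.19,3.63,1.10,5
S,16,32.06,2.58,2.90,1.04,6
Cl,17,35.45,3.16,2.18,0.99,7
K,19,39.098,0.82,43.06,1.96,1
Se,34,78.971,2.55,3.77,1.17,6
Br,35,79.904,2.96,3.05,1.14,7
I,53,126.904,2.66,5.35,1.33,7
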