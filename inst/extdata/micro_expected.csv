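# Hand-derived expected values for the micro dataset (all 8 cases treated as
# training). Descriptor: X(P)1 (first-order path connectivity,
# sum over bonds of 1/sqrt(delta_i*delta_j)).
# Element statistics (identical for the ma/tg/ei kinds by construction --
# each kind splits the 8 cases into the same two groups of 4):
#   avg over actives, condition-1 elements: 1.2071067811865475
#   avg over actives, condition-2 elements: 1.6642135623730949
#   training std (sample, n-1):             0.59912634870335235
#   ps (2 actives of 4 cases):              0.5
# d_value = (xp1 - avg_element) / (std * ps), identical for the three
# deviation features D(X(P)1)ma, D(X(P)1)tg, D(X(P)1)ei.
compound_id,xp1,ia,avg_element,d_value
M1,1.0000000000000000,1,1.2071067811865475,-0.69136262037139351
M2,1.4142135623730949,1,1.2071067811865475,0.69136262037139351
M3,1.9142135623730949,-1,1.2071067811865475,2.36045963498981370
M4,1.7320508075688774,-1,1.2071067811865475,1.75236501455304028
M5,1.4142135623730949,1,1.6642135623730949,-0.83454850730921004
M6,1.9142135623730949,1,1.6642135623730949,0.83454850730921004
M7,1.4142135623730949,-1,1.6642135623730949,-0.83454850730921004
M8,3.0000000000000000,-1,1.6642135623730949,4.45911431042168349
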