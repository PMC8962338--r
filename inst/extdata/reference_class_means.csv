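# Published class-based mean values of the deviation descriptors in the two
# reference PTML models, with the reported propensity direction (the relative
# tendency of the descriptor to increase or decrease in multi-target actives).
model,code,spec,suffix,mean_active,mean_inactive,propensity
1,DT01,NSM(Hyd)3,ma,-2.3485e-2,1.0631e-1,Decrease
1,DT02,NXv(P)4,ma,6.6912e-3,5.5922e-3,Increase
1,DT03,Ne(P)1,ma,-3.2309e-4,8.6125e-2,Decrease
1,DT04,Ne(P)2,ma,-4.7514e-2,1.4992e-1,Decrease
1,DT05,Ne(Ch)6,ma,-4.1335e-2,1.7654e-1,Decrease
1,DT06,SM(Hyd)7,tg,3.1706e-2,-2.5668e-1,Increase
1,DT07,e(Ch)5,tg,5.2858e-3,-4.9427e-2,Increase
1,DT08,NSM(Psa)1,tg,2.2379e-2,-1.9481e-2,Increase
1,DT09,NSM(Gas)3,tg,2.8122e-2,-1.3897e-1,Increase
1,DT10,NXv(P)1,tg,-1.2919e-2,1.1367e-1,Decrease
1,DT11,Xv(Ch)6,ei,-4.9125e-3,-7.1198e-2,Increase
1,DT12,NSM(Hyd)1,ei,-5.5366e-2,2.3959e-1,Decrease
1,DT13,NSM(Mol)1,ei,-4.2905e-2,2.2042e-1,Decrease
1,DT14,Ne(P)5,ei,-1.2401e-2,-5.6792e-2,Increase
1,DT15,Ne(PC)6,ei,3.4465e-2,-2.3273e-1,Increase
2,DQ01,ASq4(Hyd)G,ma,-5.4750e-3,-4.6447e-3,Decrease
2,DQ02,ASq3(Hyd)Y,ma,2.6348e-2,-1.8596e-1,Increase
2,DQ03,ASq4(Hyd)Y,ma,3.5673e-2,-1.3724e-1,Increase
2,DQ04,ASq2(E)Y,ma,5.0259e-2,-2.2849e-1,Increase
2,DQ05,ASq1(Psa)Y,ma,3.8557e-3,6.3789e-2,Decrease
2,DQ06,ASq1(Aw)C,tg,5.9744e-2,-3.4756e-1,Increase
2,DQ07,ASq0(Ku)G,tg,3.9557e-3,1.1249e-1,Decrease
2,DQ08,ASq4(Psa)Y,tg,3.1247e-2,-1.2646e-1,Increase
2,DQ09,ASq1(Hyd)G,ei,-1.1160e-2,4.0920e-2,Decrease
2,DQ10,ASq2(Hyd)G,ei,5.8725e-4,3.3683e-2,Decrease
2,DQ11,ASq2(Aw)G,ei,9.2750e-3,1.9038e-2,Decrease
2,DQ12,ASq1(Hyd)M,ei,2.6208e-2,-1.7829e-1,Increase
2,DQ13,ASq1(Ku)M,ei,2.8400e-2,-3.0151e-1,Increase
2,DQ14,ASq0(Hyd)Y,ei,1.3478e-2,-2.1995e-2,Increase
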