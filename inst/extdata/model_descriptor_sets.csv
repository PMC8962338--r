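# Descriptor sets of the two reference PTML models: raw graph-theoretical
# invariant (spec) plus the experimental-condition element (suffix) against
# which its deviation feature is computed.
model,code,spec,suffix
1,DT01,NSM(Hyd)3,ma
1,DT02,NXv(P)4,ma
1,DT03,Ne(P)1,ma
1,DT04,Ne(P)2,ma
1,DT05,Ne(Ch)6,ma
1,DT06,SM(Hyd)7,tg
1,DT07,e(Ch)5,tg
1,DT08,NSM(Psa)1,tg
1,DT09,NSM(Gas)3,tg
1,DT10,NXv(P)1,tg
1,DT11,Xv(Ch)6,ei
1,DT12,NSM(Hyd)1,ei
1,DT13,NSM(Mol)1,ei
1,DT14,Ne(P)5,ei
1,DT15,Ne(PC)6,ei
2,DQ01,ASq4(Hyd)G,ma
2,DQ02,ASq3(Hyd)Y,ma
2,DQ03,ASq4(Hyd)Y,ma
2,DQ04,ASq2(E)Y,ma
2,DQ05,ASq1(Psa)Y,ma
2,DQ06,ASq1(Aw)C,tg
2,DQ07,ASq0(Ku)G,tg
2,DQ08,ASq4(Psa)Y,tg
2,DQ09,ASq1(Hyd)G,ei
2,DQ10,ASq2(Hyd)G,ei
2,DQ11,ASq2(Aw)G,ei
2,DQ12,ASq1(Hyd)M,ei
2,DQ13,ASq1(Ku)M,ei
2,DQ14,ASq0(Hyd)Y,ei
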