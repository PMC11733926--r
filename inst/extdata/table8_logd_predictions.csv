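formula,smiles,expt,pred
C_8_H_16_N_4_S,CC(C)N(C(C)C)c1nnc(N)s1,-0.59065,-0.58704
C_19_H_23_FN_4_O_2_,Cc1ccc(COC(=O)N2CC[C@H](CNc3ncccn3)[C@H](F)C2)cc1,0.84776,0.85311
C_9_H_13_N_3_O,CC(C)NNC(=O)c1ccncc1,-1.56074,-1.54842
C_18_H_16_FNO_6_S_2_,Cc1c(CC(=O)O)c2cc(F)ccc2n1S(=O)(=O)c3ccc(cc3)S(=O)(=O)C,-2.20469,-2.22211
C_28_H_26_F_3_N_3_O_7_,CC(C)C(NC(=O)CN1C(=O)C(=CC=C1c2ccccc2)NC(=O)OCc3ccc(cc3)C(=O)O)C(=O)C(F)(F)F,-1.13424,-1.12462
C_26_H_23_N_5_O,C[C@@H](NC1=CC(=O)CC1)c2ccc(Nc3ncc4cc(ccc4n3)c5ccncc5)cc2,0.83940,0.83187
C_15_H_18_N_4_O_2_S_2_,NC(=O)Nc1sc(cc1C(=O)N[C@H]2CCCNC2)c3ccsc3,-0.95025,-0.95886
C_21_H_18_ClN_5_O_4_,CN(C)C(=O)Nc1ccc(CN2NC(=O)C3=C(C2=O$C(=O)c4ccc(Cl)cc4N3)cc1,-0.91680,-0.90843
C_25_H_26_ClN_7_O_3_,COc1cc(ccc1Nc2ncc(Cl)c(n2)c3cnc4cc(CO)ccn34)N5CCN(CC5)C(=O)C,0.75577,0.76341
C_10_H_14_N_2_,CN1CCCC1c2cccnc2,-1.41858,-1.43342
C_15_H_22_FN_3_O_4_S,CC(C)(CS(=O)(=O)N1CCN(CC1)c2ccc(F)cc2)N(O)C=O,-0.94189,-0.95268
C_24_H_29_F_3_N_2_O_3_S,CCN(C1CCN(Cc2ccc(cc2)C(F)(F)F)CC1)C(=O)Cc3ccc(cc3)S(=O)(=O)C,0.58852,0.58044
C_23_H_29_N_3_O_5_S,CN(CCNC[C@H](O)c1ccc(O)c2NC(=O)Sc12)C(=O)CCOCCc3ccccc3,-0.82481,-0.83644
C_25_H_28_F_3_N_3_O_2_,COc1ccc2c(C)cc(N[C@H]3CCC[C@@H](C3)NCc4cccc(OC(F)(F)F)c4)nc2c1,1.18228,1.16486
C_24_H_29_Cl_2_N_3_O_5_S,COc1ccc(cc1)S(=O)(=O)NC(=O)N2CCC(CC2)N3CCC(CC3)Oc4ccc(Cl)c(Cl)c4,-0.67428,-0.68564
C_25_H_30_N_6_O_2_,CN(c1ccccc1)c2ccnc(Nc3cc(cc(c3)N4CCOCC4)N5CCOCC5)n2,1.06520,1.04686
C_15_H_17_F_4_N_5_O_4_,C[C@H]1O[C@H]([C@H](O)[C@@H]1O)n2cnc3c(N)nc(OCC4CC(F)(F)C4(F)F)nc23,-0.64919,-0.63778
C_24_H_23_Cl_2_N_3_O_4_,OC(=O)[C@H](Cc1cccc(OCCCNc2ccccn2)c1)NC(=O)c3c(Cl)cccc3Cl,-1.70291,-1.73467
C_22_H_23_F_5_N_6_O_3_S,OC[C@H]1C[C@H]([C@H](O)[C@@H]1O)n2nnc3c(N[C@@H]4C[C@H]4c5ccc(F)c(F)c5)nc(SCCC(F)(F)F)nc23,1.50007,1.53064
C_18_H_16_ClNO_4_S_2_,Cc1c(Sc2ccc(Cl)cc2)c3cc(ccc3n1CC(=O)O)S(=O)(=O)C,-1.38512,-1.35537
C_25_H_27_N_5_O_4_,O[C@@H]1CN(CCN2C(=O)C=Cc3ccc(cc23)C#N)CC[C@@H]1NCc4cc5OCCOc5cn4,-1.45203,-1.41925
C_8_H_8_N_4_O,NNC1=Nc2ccccc2NC1=O,-1.46875,-1.43553
C_24_H_25_N_3_O_3_,COc1ccc(cc1)C(=O)Nc2cc(NC(=O)c3cccc(c3)N(C)C)ccc2C,0.81431,0.79583
C_25_H_31_N_5_O_3_,C[C@@H]1CN(CCN1C(=O)[C@@H]2CCCC[C@H]2C(=O)NC3(CC3)C#N)c4ccc5c(C)noc5c4,0.39617,0.38714
C_26_H_23_F_2_N_3_O_3_,C[C@H](NC(=O)Cc1cc(F)cc(F)c1)C$=O)NC2C(=O)N(C)c3ccccc3c4ccccc24,1.17392,1.14022
C_22_H_27_ClN_2_O_5_S,C[C@H]1CN(Cc2cc(Cl)ccc2OC(C)(C)C(=O)O)CCN1S(=O)(=O)c3ccccc3,-1.38512,-1.42671
C_16_H_13_F_3_O_4_,COc1ccc(cc1)c2cc(ccc2OCC(=O)O)C(F)(F)F,-1.59420,-1.64238
C_13_H_18_ClNO_2_,C[C@@H]1NC(C)(C)CO[C@@]1(O)c2cccc(Cl)c2,-0.42339,-0.41045
C_11_H_12_F_3_N_5_,FC(F)(F)c1nnc2ccc(nn12)N3CCCCC3,0.67214,0.64994
C_19_H_15_ClN_4_O_3_,CCC(N1NC(=O)c2nc3cc(Cl)ccc3c(O)c2C1=O)c4cccnc4,-1.25132,-1.20065
C_20_H_21_FN_2_O,CN(C)CCCC1(OCc2cc(ccc12)C#N)c3ccc(F)cc3,-0.53211,-0.55394
C_20_H_19_ClN_4_O_5_,COc1cc(Nc2cc(Nc3c(Cl)ccc4OCOc34)ncn2)cc(OC)c1OC,0.73068,0.76155
C_13_H_9_FN_2_,Fc1ccc(cc1)c2cn3ccccc3n2,0.75577,0.78804
C_23_H_25_ClN_4_O_2_S,Cc1sc2c(C(=N[C@@H](CC(=O)OC(C)(C)C)c3nnc(C)n23)c4ccc(Cl)cc4)c1C,1.35790,1.41848
C_15_H_16_Cl_2_N_4_O_3_S,Cc1[nH]c(C(=O)NC2CCN(CC2)c3nc(cs3)C(=O)O)c(Cl)c1Cl,-1.71964,-1.80957
C_6_H_11_NO,O=C1CCCCCN1,-1.90362,-2.00360
C_25_H_24_F_3_N_3_O_5_,CC1=CN([C@H]2CCCN(Cc3ccc(C(=O)O)c(Oc4cccc(c4)C(F)(F)F)c3)C2)C(=O)NC1=O,-2.15451,-2.04005
C_31_H_36_ClN_3_O_5_,CC1=CN([C@H]2CCCN(C2)[C@H](CC3CCCCC3)c4ccc(C(=O)O)c(Oc5cccc(Cl)c5)c4)C(=O)NC1=O,-0.30631,-0.29003
C_23_H_25_BrN_4_O,CO[C@@H]1CC[C@@]2(CC1)Cc3ccc(cc3C24N=C(C)C(=N4)N)c5cncc(Br)c5,1.00666,0.95149
C_11_H_20_N_2_O_2_,CC(C)(C)C(=O)N[C@H]1CCCCNC1=O,-1.35167,-1.26705
C_26_H_24_N_2_O_3_S,CC[C@H](NC(=O)c1c(c(nc2ccccc12)c3ccccc3)S(=O)(=O)C)c4ccccc4,0.81431,0.86580
C_17_H_17_N_3_O_2_,COc1cc2ncnc(NCc3ccccc3)c2cc1OC,0.91467,0.97275
C_20_H_21_F_3_N_2_O_5_S,OC(=O)COc1ccc(cc1CN2CCN(CC2)S(=O)(=O)c3ccccc3)C(F)(F)F,-1.50220,-1.59854
C_15_H_11_FN_4_O_2_,OC(=O)c1ccc(cc1)c2nnn(Cc3ccccc3F)n2,-1.58583,-1.68813
C_24_H_22_N_4_O_2_,COc1ccc(Nc2cc(Oc3cc(C)c(C)nc3c4ccccn4)ccn2)cc1,1.09865,1.01593
C_16_H_14_ClFO_5_S,CCS(=O)(=O)c1ccc(c(F)c1)c2cc(Cl)ccc2OCC(=O)O,-2.60610,-2.40706
C_22_H_28_ClN_3_O_3_S_2_,O[C@@H](CNCCCSCCNCCc1cccc(Cl)c1)c2ccc(O)c3NC(=O)Sc23,-0.95025,-1.02418
C_21_H_25_N_3_O_2_S,O=S(=O)(NCC(N1CCCCCC1)c2ccccc2)c3ccc(cc3)C#N,0.55506,0.51115
C_21_H_25_ClFN_7_O_2_,C[C@H](Nc1nc(NC[C@@H](O)CO)c(Cl)c(Nc2cc([nH]n2)C3CC3)n1)c4ccc(F)cc4,0.99830,0.91922
C_16_H_18_N_2_,CN1C[C@@H](c2ccccc2)c3cccc(N)c3C1,-0.07215,-0.07852
C_7_H_8_N_2_O,CC(=O)Nc1ccccn1,-1.41858,-1.54491
C_25_H_29_F_3_N_2_O_2_S_2_,CC(C)CN1C(=O)N(C)C(=O)c2c(SC3CCCCC3)c(Cc4ccccc4C(F)(F)F)sc12,1.62551,1.77093
C_22_H_25_F_3_N_2_O_4_S,CC(C)Oc1ccc(cc1C(=O)N2CCN(CC2)c3ccc(cc3)C(F)(F)F)S(=O)(=O)C,0.94812,1.03297
C_20_H_15_F_3_N_4_O_3_,NC1C2CN(CC12)c3nc4N(C=C(C(=O)O)C(=O)c4cc3F)c5ccc(F)cc5F,-1.58583,-1.44289
C_18_H_15_F2N_3_O_3_,COc1cc2ncc(C(=O)N)c(Nc3ccc(F)cc3F)c2cc1OC,0.63033,0.56239
C_21_H_27_N_3_O_3_S,CCCSc1c(cnn1c2ccc(cc2)C(=O)O)C(=O)N(C)C3CCCCC3,-1.34331,-1.19841
C_27_H_34_N_6_O_2_,CN(c1ccnc(Nc2cc(cc(c2)N3CCOCC3)N4CCCC4)n1)c5cc(CO)ccc5C,1.34117,1.48598
C_18_H_20_Cl_2_N_2_O_5_S,CNC(=O)OC[C@@H](C)N(c1cc(Cl)ccc1CO)S(=O)(=O)c2ccc(Cl)cc2,0.67214,0.59870
C_17_H_17_N_3_O_2_,COc1cc2ncnc(Nc3cccc(C)c3)c2cc1OC,1.09029,0.97053
C_20_H_20_ClNO_2_,Cc1ccc(cc1)C(=O)N2CCC(CC2)C(=O)c3ccc(Cl)cc3,1.33281,1.17617
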