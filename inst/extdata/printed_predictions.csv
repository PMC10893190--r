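table,parent,analyte,population,route,amount,per_kg,infusion_min,metric,pre_value,obs_value,pre_cmax,obs_cmax
4,enalapril,enalapril,healthy,oral,10,0,0,auc,0.1467,0.1229,45.6,66.9
4,enalapril,enalapril,CP-B,oral,10,0,0,auc,0.2253,0.1761,60.6,110.1
4,enalapril,enalapril,CP-C,oral,10,0,0,auc,0.3195,0.2769,80.7,123.4
4,enalapril,enalaprilat,healthy,oral,10,0,0,auc,0.3683,0.3754,39.7,46.1
4,enalapril,enalaprilat,CP-B,oral,10,0,0,auc,0.5154,0.3812,35.1,36.8
4,enalapril,enalaprilat,CP-C,oral,10,0,0,auc,0.2476,0.1733,20.1,16.8
5,benazepril,benazepril,healthy,oral,10,0,0,auc,0.2571,0.1390,113.545,139.139
5,benazepril,benazepril,healthy,oral,20,0,0,auc,0.4611,0.2195,227.089,265.313
5,benazepril,benazepril,CP-B,oral,20,0,0,auc,0.5883,0.6159,268.130,543.472
5,benazepril,benazeprilat,healthy,oral,10,0,0,auc,1.6492,1.5330,198.97,188.704
5,benazepril,benazeprilat,healthy,oral,20,0,0,auc,2.7107,2.3800,397.95,463.830
5,benazepril,benazeprilat,CP-B,oral,20,0,0,auc,2.3870,2.1650,344.85,345.010
6,cilazapril,cilazapril,healthy,oral,1,0,0,auc,0.1044,0.0998,26.2,33.9
6,cilazapril,cilazapril,healthy,oral,2.5,0,0,auc,0.2610,0.2560,65.4,82.7
6,cilazapril,cilazapril,healthy,oral,5,0,0,auc,0.5221,0.4960,130.8,182.0
6,cilazapril,cilazapril,CP-B,oral,1,0,0,auc,0.1201,0.1840,28.3,40.0
6,cilazapril,cilazaprilat,healthy,oral,1,0,0,auc,0.0725,0.0791,10.2,12.4
6,cilazapril,cilazaprilat,healthy,oral,1.25,0,0,auc,0.0906,0.070,12.7,13.0
6,cilazapril,cilazaprilat,healthy,oral,2.5,0,0,auc,0.1811,0.175,25.4,37.7
6,cilazapril,cilazaprilat,healthy,oral,5,0,0,auc,0.3623,0.342,50.8,94.2
6,cilazapril,cilazaprilat,healthy,oral,10,0,0,auc,0.7246,0.550,101.5,165.0
6,cilazapril,cilazaprilat,CP-B,oral,1,0,0,auc,0.0695,0.0775,8.3,10.2
7,perindopril,perindopril,healthy,oral,4,0,0,auc,0.120,0.121,34.6,64.2
7,perindopril,perindopril,CP-A,oral,8,0,0,auc,0.239,0.377,70.4,NA
7,perindopril,perindopril,CP-B,oral,8,0,0,auc,0.281,0.602,77.0,NA
7,perindopril,perindoprilat,healthy,oral,4,0,0,auc,0.0681,0.0520,4.3,4.7
7,perindopril,perindoprilat,healthy,oral,8,0,0,auc,0.1362,0.1197,8.5,NA
7,perindopril,perindoprilat,CP-A,oral,8,0,0,auc,0.2695,0.3210,8.8,29
7,perindopril,perindoprilat,CP-B,oral,8,0,0,auc,0.2777,0.1340,8.6,NA
8,temocapril,temocapril,healthy,oral,1,0,0,auc,0.0257,NA,11.0,NA
8,temocapril,temocapril,CP-B,oral,1,0,0,auc,0.0271,NA,11.6,NA
8,temocapril,temocaprilat,healthy,oral,1,0,0,auc,0.1199,0.1230,11.2,15.8
8,temocapril,temocaprilat,CP-B,oral,1,0,0,auc,0.0800,0.1714,7.4,14.3
9,oseltamivir,oseltamivir,healthy,oral,75,0,0,auc,0.1430,0.1590,59.8,74.4
9,oseltamivir,oseltamivir,healthy,oral,150,0,0,auc,0.2860,0.3130,119.5,192.0
9,oseltamivir,oseltamivir,CP-B,oral,75,0,0,auc,0.1985,0.2100,85.6,100.0
9,oseltamivir,oseltamivir_carboxylate,healthy,oral,75,0,0,auc,2.5068,3.0200,264.93,291.00
9,oseltamivir,oseltamivir_carboxylate,healthy,oral,150,0,0,auc,5.0135,6.3100,529.86,550.00
9,oseltamivir,oseltamivir_carboxylate,CP-B,oral,75,0,0,auc,4.3235,3.1000,279.86,260.00
10,flumazenil,flumazenil,healthy,iv_infusion,10,0,1,cl,0.4486,0.9000,NA,NA
10,flumazenil,flumazenil,healthy,iv_infusion,10,0,10,cl,0.4549,0.8967,NA,NA
10,flumazenil,flumazenil,healthy,iv_infusion,2.5,0,0.5,cl,0.4766,0.7160,NA,NA
10,flumazenil,flumazenil,CP-B,iv_infusion,2,0,5,cl,0.4988,0.4932,NA,NA
10,flumazenil,flumazenil,CP-C,iv_infusion,2,0,5,cl,0.4030,0.3165,NA,NA
10,flumazenil,flumazenil,CP-C,iv_infusion,2,0,1,cl,0.4295,0.7050,NA,NA
10,flumazenil,flumazenil,healthy,oral,30,0,0,auc,0.1741,NA,71.0,70.1
10,flumazenil,flumazenil,CP-C,oral,30,0,0,auc,0.5139,NA,174.7,258.0
11,pethidine,pethidine,healthy,iv_infusion,25,0,1,cl,0.4956,0.5624,NA,NA
11,pethidine,pethidine,healthy,iv_infusion,50,0,1,cl,0.7784,1.0200,NA,NA
11,pethidine,pethidine,healthy,iv_infusion,70,0,2,cl,0.4952,0.7505,NA,NA
11,pethidine,pethidine,healthy,iv_infusion,0.8,1,1,cl,0.7887,1.3160,NA,NA
11,pethidine,pethidine,healthy,iv_infusion,0.8,1,5,cl,0.6972,0.9000,NA,NA
11,pethidine,pethidine,CP-A,iv_infusion,0.8,1,1,cl,0.5349,0.3920,NA,NA
11,pethidine,pethidine,CP-A,iv_infusion,0.8,1,5,cl,0.7560,0.5730,NA,NA
11,pethidine,pethidine,CP-B,iv_infusion,0.8,1,1,cl,0.5724,0.3730,NA,NA
11,pethidine,pethidine,healthy,oral,25,0,0,cl,0.8563,0.9270,36.0,NA
11,pethidine,pethidine,healthy,oral,100,0,0,auc,0.6097,0.8600,143.9,170.0
11,pethidine,pethidine,healthy,oral,0.8,1,0,auc,0.4649,NA,80.6,NA
11,pethidine,pethidine,CP-A,oral,1.6,1,0,auc,1.2681,NA,157.0,NA
11,pethidine,pethidine,CP-A,oral,0.8,1,0,auc,0.4439,NA,78.5,NA
11,pethidine,pethidine,CP-B,oral,1.6,1,0,auc,1.1983,NA,146.3,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.05,1,0,auc,0.0536,0.0447,NA,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.075,1,0,auc,0.0787,0.0665,NA,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.1,1,0,auc,0.1000,0.0860,NA,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.2,1,0,auc,0.2145,0.1683,NA,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.3,1,0,auc,0.2960,0.2517,NA,NA
12,remimazolam,remimazolam,healthy,iv_bolus,0.4,1,0,auc,0.3979,0.3317,NA,NA
12,remimazolam,remimazolam,CP-B,iv_bolus,10.4,0,0,auc,0.1277,NA,NA,NA
12,remimazolam,remimazolam,CP-C,iv_bolus,8.2,0,0,auc,0.0805,NA,NA,NA
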