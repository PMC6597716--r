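enzyme,table,temperature_C,Km_IPM_uM,Km_IPM_se,Km_IPM_rel,Km_NAD_uM,Km_NAD_se,Km_NAD_rel,kcat_per_s,kcat_se,kcat_rel
TtIPMDH,T1,25,NA,NA,NA,2.2,0.3,1.0,0.37,0.01,1.0
mut#3,T1,25,NA,NA,NA,19,5,8.6,1.1,0.1,3.0
mut#5,T1,25,NA,NA,NA,200,40,91,1.3,0.1,3.5
mut#9,T1,25,NA,NA,NA,27,1,12,3.5,0.0,9.5
mut#11,T1,25,NA,NA,NA,74,8,34,2.9,0.1,7.8
mut#15,T1,25,NA,NA,NA,150,20,68,0.55,0.03,1.5
mut#17,T1,25,NA,NA,NA,16,4,7.3,0.66,0.04,1.8
mut#18,T1,25,NA,NA,NA,7.0,0.7,3.2,0.36,0.00,0.97
mut#20,T1,25,NA,NA,NA,92,24,42,0.66,0.06,1.8
mut#21,T1,25,NA,NA,NA,8.6,1.5,3.9,0.70,0.02,1.9
mut#28,T1,25,NA,NA,NA,560,70,250,3.3,0.2,8.9
EcIPMDH,T1,25,NA,NA,NA,62,4,28,13,0.3,35
TtIPMDH,T2,25,NA,NA,NA,2.2,0.3,1.0,0.37,0.01,1.0
mut9/17,T2,25,NA,NA,NA,51,3,24,4.2,0.1,11
mut9/21,T2,25,NA,NA,NA,100,10,48,4.3,0.1,12
EcIPMDH,T2,25,NA,NA,NA,62,4,57,13,0,34
TtIPMDH,T2,40,2.3,0.8,1.0,12,1,1.0,2.4,0.1,1.0
mut9/17,T2,40,1.7,0.3,0.75,110,10,9.3,15,0,6.2
mut9/21,T2,40,3.0,0.7,1.3,220,10,19,16,0,6.8
EcIPMDH,T2,40,4.0,0.6,1.7,170,20,14,56,2,23
TtIPMDH,T2,70,3.7,1.4,1.0,210,10,1.0,79,3,1.0
mut9/17,T2,70,3.3,1.9,0.89,1200,100,5.9,80,2,1.0
mut9/21,T2,70,3.6,1.8,0.96,1600,300,7.5,100,10,1.3
EcIPMDH,T2,70,34,4,9.2,1200,100,6.0,190,10,2.3
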