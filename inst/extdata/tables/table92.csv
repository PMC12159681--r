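row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table92_r01,t1_native_myo,all,0,18,all,GE MOLLI 3b(3s)3b(3s)5b,1.5,not_applicable,32,1017,48,921,1113,single_study_mean_2sd,0,normal
table92_r02,t1_native_myo,all,0,18,all,GE SmartT1map saturation recovery,1.5,not_applicable,34,1191,62,1067,1315,single_study_mean_2sd,0,normal
table92_r03,t1_native_myo,all,0,18,all,Siemens MOLLI 5b(3s)3b,1.5,not_applicable,46,1005,40,925,1085,single_study_mean_2sd,0,normal
table92_r04,t1_native_myo,all,0,18,all,Philips MOLLI 5s(3s)3s,3,not_applicable,119,1241,35,1171,1311,single_study_mean_2sd,0,normal
table92_r05,t1_native_myo,all,0,18,all,Siemens MOLLI 5s(3s)3s,3,not_applicable,38,1223,29,1165,1281,single_study_mean_2sd,0,normal
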