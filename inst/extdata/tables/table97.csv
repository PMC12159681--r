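row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table97_r01,t2_myo,all,0,18,all,Siemens T2 GraSE,3,not_applicable,38,43.0,4.5,34,52,single_study_mean_2sd,0,normal
table97_r02,t2_myo,all,0,18,all,Philips T2 GraSE,3,not_applicable,118,44.8,2.9,39,51,single_study_mean_2sd,0,normal
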