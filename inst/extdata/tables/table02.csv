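row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table02_r01,lvedv,male,18,,all,,,papillary_in_mass,6213,147,33,83,211,pooled_frequentist,0,normal
table02_r02,lvedv,female,18,,all,,,papillary_in_mass,7269,118,24,72,164,pooled_frequentist,0,normal
table02_r03,lvedv_bsa,male,18,,all,,,papillary_in_mass,6485,75,15,46,104,pooled_frequentist,0,normal
table02_r04,lvedv_bsa,female,18,,all,,,papillary_in_mass,7538,69,11,46,91,pooled_frequentist,0,normal
table02_r05,lvesv,male,18,,all,,,papillary_in_mass,6206,51,16,20,82,pooled_frequentist,0,normal
table02_r06,lvesv,female,18,,all,,,papillary_in_mass,7264,39,11,17,60,pooled_frequentist,0,normal
table02_r07,lvesv_bsa,male,18,,all,,,papillary_in_mass,6471,26,8,11,41,pooled_frequentist,0,normal
table02_r08,lvesv_bsa,female,18,,all,,,papillary_in_mass,7538,23,6,11,34,pooled_frequentist,0,normal
table02_r09,lvsv,male,18,,all,,,papillary_in_mass,6158,98,23,53,142,pooled_frequentist,0,normal
table02_r10,lvsv,female,18,,all,,,papillary_in_mass,7214,79,16,47,111,pooled_frequentist,0,normal
table02_r11,lvsv_bsa,male,18,,all,,,papillary_in_mass,6312,50,10,30,69,pooled_frequentist,0,normal
table02_r12,lvsv_bsa,female,18,,all,,,papillary_in_mass,7372,47,8,31,63,pooled_frequentist,0,normal
table02_r13,lvef,male,18,,all,,,papillary_in_mass,6472,66,7,53,79,pooled_frequentist,0,normal
table02_r14,lvef,female,18,,all,,,papillary_in_mass,7541,67,6,55,80,pooled_frequentist,0,normal
table02_r15,lvm,male,18,,all,,,papillary_in_mass,6205,124,23,78,169,pooled_frequentist,0,normal
table02_r16,lvm,female,18,,all,,,papillary_in_mass,7261,87,18,52,123,pooled_frequentist,0,normal
table02_r17,lvm_bsa,male,18,,all,,,papillary_in_mass,6374,64,10,44,84,pooled_frequentist,0,normal
table02_r18,lvm_bsa,female,18,,all,,,papillary_in_mass,7463,52,9,35,69,pooled_frequentist,0,normal
table02_r19,lvco,male,18,,all,,,papillary_in_mass,4719,5.5,1.4,2.6,8.3,pooled_frequentist,1,normal
table02_r20,lvco,female,18,,all,,,papillary_in_mass,4794,4.7,1.1,2.6,6.9,pooled_frequentist,1,normal
table02_r21,lvci,male,18,,all,,,papillary_in_mass,100,3.2,0.8,1.6,4.8,pooled_frequentist,1,normal
table02_r22,lvci,female,18,,all,,,papillary_in_mass,100,3.0,,2.6,3.6,pooled_frequentist,1,median_iqr
table02_r23,lvm_lvedv,male,18,,all,,,papillary_in_mass,1310,0.8,0.2,0.5,1.1,pooled_frequentist,1,normal
table02_r24,lvm_lvedv,female,18,,all,,,papillary_in_mass,2305,0.7,0.1,0.4,1.0,pooled_frequentist,1,normal
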