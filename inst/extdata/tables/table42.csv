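row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table42_r01,lvedv_bsa,male,18,,all,elite athletes,,papillary_in_mass,101,101,12,77,125,single_study_mean_2sd,0,normal
table42_r02,lvedv_bsa,female,18,,all,elite athletes,,papillary_in_mass,49,89,10,69,109,single_study_mean_2sd,0,normal
table42_r03,lvesv_bsa,male,18,,all,elite athletes,,papillary_in_mass,101,35,7,21,49,single_study_mean_2sd,0,normal
table42_r04,lvesv_bsa,female,18,,all,elite athletes,,papillary_in_mass,49,30,7,16,44,single_study_mean_2sd,0,normal
table42_r05,lvsv_bsa,male,18,,all,elite athletes,,papillary_in_mass,101,66,8,50,82,single_study_mean_2sd,0,normal
table42_r06,lvsv_bsa,female,18,,all,elite athletes,,papillary_in_mass,49,59,7,45,73,single_study_mean_2sd,0,normal
table42_r07,lvm_bsa,male,18,,all,elite athletes,,papillary_in_mass,101,113,17,79,147,single_study_mean_2sd,0,normal
table42_r08,lvm_bsa,female,18,,all,elite athletes,,papillary_in_mass,49,84,12,60,108,single_study_mean_2sd,0,normal
table42_r09,lvef,male,18,,all,elite athletes,,papillary_in_mass,101,66,5,56,76,single_study_mean_2sd,0,normal
table42_r10,lvef,female,18,,all,elite athletes,,papillary_in_mass,49,66,6,54,78,single_study_mean_2sd,0,normal
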