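row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table41_r01,lvedv,male,18,,all,regular athletes,,papillary_in_volume,83,250,32,186,314,single_study_mean_2sd,0,normal
table41_r02,lvedv,female,18,,all,regular athletes,,papillary_in_volume,60,194,27,140,248,single_study_mean_2sd,0,normal
table41_r03,lvedv,male,18,,all,elite athletes,,papillary_in_volume,46,261,39,183,339,single_study_mean_2sd,0,normal
table41_r04,lvedv,female,18,,all,elite athletes,,papillary_in_volume,33,199,31,137,261,single_study_mean_2sd,0,normal
table41_r05,lvedv_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,123,13,97,149,single_study_mean_2sd,0,normal
table41_r06,lvedv_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,107,14,79,135,single_study_mean_2sd,0,normal
table41_r07,lvedv_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,129,17,95,163,single_study_mean_2sd,0,normal
table41_r08,lvedv_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,107,14,79,135,single_study_mean_2sd,0,normal
table41_r09,lvesv,male,18,,all,regular athletes,,papillary_in_volume,83,108,20,68,148,single_study_mean_2sd,0,normal
table41_r10,lvesv,female,18,,all,regular athletes,,papillary_in_volume,60,86,15,56,116,single_study_mean_2sd,0,normal
table41_r11,lvesv,male,18,,all,elite athletes,,papillary_in_volume,46,117,24,69,165,single_study_mean_2sd,0,normal
table41_r12,lvesv,female,18,,all,elite athletes,,papillary_in_volume,33,85,20,45,125,single_study_mean_2sd,0,normal
table41_r13,lvesv_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,53,9,35,71,single_study_mean_2sd,0,normal
table41_r14,lvesv_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,48,8,32,64,single_study_mean_2sd,0,normal
table41_r15,lvesv_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,58,11,36,80,single_study_mean_2sd,0,normal
table41_r16,lvesv_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,46,11,24,68,single_study_mean_2sd,0,normal
table41_r17,lvm,male,18,,all,regular athletes,,papillary_in_volume,83,125,22,81,169,single_study_mean_2sd,0,normal
table41_r18,lvm,female,18,,all,regular athletes,,papillary_in_volume,60,84,17,50,118,single_study_mean_2sd,0,normal
table41_r19,lvm,male,18,,all,elite athletes,,papillary_in_volume,46,139,28,83,195,single_study_mean_2sd,0,normal
table41_r20,lvm,female,18,,all,elite athletes,,papillary_in_volume,33,92,15,62,122,single_study_mean_2sd,0,normal
table41_r21,lvm_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,62,11,40,84,single_study_mean_2sd,0,normal
table41_r22,lvm_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,46,9,28,64,single_study_mean_2sd,0,normal
table41_r23,lvm_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,69,13,43,95,single_study_mean_2sd,0,normal
table41_r24,lvm_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,50,8,34,66,single_study_mean_2sd,0,normal
table41_r25,lvef,male,18,,all,regular athletes,,papillary_in_volume,83,57,5,47,67,single_study_mean_2sd,0,normal
table41_r26,lvef,female,18,,all,regular athletes,,papillary_in_volume,60,55,4,47,63,single_study_mean_2sd,0,normal
table41_r27,lvef,male,18,,all,elite athletes,,papillary_in_volume,46,55,5,45,65,single_study_mean_2sd,0,normal
table41_r28,lvef,female,18,,all,elite athletes,,papillary_in_volume,33,58,7,44,72,single_study_mean_2sd,0,normal
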