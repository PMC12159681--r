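row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table43_r01,rvedv,male,18,,all,regular athletes,,papillary_in_volume,83,277,36,205,349,single_study_mean_2sd,0,normal
table43_r02,rvedv,female,18,,all,regular athletes,,papillary_in_volume,60,209,29,151,267,single_study_mean_2sd,0,normal
table43_r03,rvedv,male,18,,all,elite athletes,,papillary_in_volume,46,291,48,195,387,single_study_mean_2sd,0,normal
table43_r04,rvedv,female,18,,all,elite athletes,,papillary_in_volume,33,219,35,149,289,single_study_mean_2sd,0,normal
table43_r05,rvedv_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,136,16,104,168,single_study_mean_2sd,0,normal
table43_r06,rvedv_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,115,15,85,145,single_study_mean_2sd,0,normal
table43_r07,rvedv_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,144,20,104,184,single_study_mean_2sd,0,normal
table43_r08,rvedv_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,118,17,84,152,single_study_mean_2sd,0,normal
table43_r09,rvesv,male,18,,all,regular athletes,,papillary_in_volume,83,135,25,85,185,single_study_mean_2sd,0,normal
table43_r10,rvesv,female,18,,all,regular athletes,,papillary_in_volume,60,102,17,68,136,single_study_mean_2sd,0,normal
table43_r11,rvesv,male,18,,all,elite athletes,,papillary_in_volume,46,148,30,88,208,single_study_mean_2sd,0,normal
table43_r12,rvesv,female,18,,all,elite athletes,,papillary_in_volume,33,103,24,55,151,single_study_mean_2sd,0,normal
table43_r13,rvesv_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,66,12,42,90,single_study_mean_2sd,0,normal
table43_r14,rvesv_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,57,9,39,75,single_study_mean_2sd,0,normal
table43_r15,rvesv_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,73,13,47,99,single_study_mean_2sd,0,normal
table43_r16,rvesv_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,56,13,30,82,single_study_mean_2sd,0,normal
table43_r17,rvm,male,18,,all,regular athletes,,papillary_in_volume,83,29,6,17,41,single_study_mean_2sd,0,normal
table43_r18,rvm,female,18,,all,regular athletes,,papillary_in_volume,60,23,4,15,31,single_study_mean_2sd,0,normal
table43_r19,rvm,male,18,,all,elite athletes,,papillary_in_volume,46,30,6,18,42,single_study_mean_2sd,0,normal
table43_r20,rvm,female,18,,all,elite athletes,,papillary_in_volume,33,25,5,15,35,single_study_mean_2sd,0,normal
table43_r21,rvm_bsa,male,18,,all,regular athletes,,papillary_in_volume,83,14,3,8,20,single_study_mean_2sd,0,normal
table43_r22,rvm_bsa,female,18,,all,regular athletes,,papillary_in_volume,60,13,2,9,17,single_study_mean_2sd,0,normal
table43_r23,rvm_bsa,male,18,,all,elite athletes,,papillary_in_volume,46,15,2,11,19,single_study_mean_2sd,0,normal
table43_r24,rvm_bsa,female,18,,all,elite athletes,,papillary_in_volume,33,14,3,8,20,single_study_mean_2sd,0,normal
table43_r25,rvef,male,18,,all,regular athletes,,papillary_in_volume,83,51,4,43,59,single_study_mean_2sd,0,normal
table43_r26,rvef,female,18,,all,regular athletes,,papillary_in_volume,60,51,4,43,59,single_study_mean_2sd,0,normal
table43_r27,rvef,male,18,,all,elite athletes,,papillary_in_volume,46,50,4,42,58,single_study_mean_2sd,0,normal
table43_r28,rvef,female,18,,all,elite athletes,,papillary_in_volume,33,53,7,39,67,single_study_mean_2sd,0,normal
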