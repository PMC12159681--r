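row_id,parameter_id,sex,age_lo,age_hi,ethnicity,group,field_strength,convention,n,mean,sd,lower,upper,method,precision,distribution
table83_r01,mpa_diam_sys,male,18,,all,,,not_applicable,60,27.4,2.6,22,33,single_study_mean_2sd,0,normal
table83_r02,mpa_diam_sys,female,18,,all,,,not_applicable,60,25.3,2.6,20,31,single_study_mean_2sd,0,normal
table83_r03,mpa_diam_dia,male,18,,all,,,not_applicable,60,22.9,2.4,18,28,single_study_mean_2sd,0,normal
table83_r04,mpa_diam_dia,female,18,,all,,,not_applicable,60,21.2,2.1,17,25,single_study_mean_2sd,0,normal
table83_r05,mpa_area_sys,male,18,,all,,,not_applicable,60,5.9,1.1,3.7,8.1,single_study_mean_2sd,1,normal
table83_r06,mpa_area_sys,female,18,,all,,,not_applicable,60,5.0,1.0,3.0,7.0,single_study_mean_2sd,1,normal
table83_r07,mpa_area_dia,male,18,,all,,,not_applicable,60,4.2,0.8,2.6,5.8,single_study_mean_2sd,1,normal
table83_r08,mpa_area_dia,female,18,,all,,,not_applicable,60,3.6,0.7,2.2,5.0,single_study_mean_2sd,1,normal
table83_r09,mpa_distension,male,18,,all,,,not_applicable,60,42.7,17.2,8,77,single_study_mean_2sd,0,normal
table83_r10,mpa_distension,female,18,,all,,,not_applicable,60,41.8,15.7,10,73,single_study_mean_2sd,0,normal
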