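table_id,parameter_id,sex,covariate,cov_value,L,M,S,c03,c10,c25,c50,c75,c90,c97,centiles_consistent
table36,la_maxvol_bsa,male,age_years,6,1.378,36.715,0.263,14,23,30,37,43,49,55,TRUE
table36,la_maxvol_bsa,male,age_years,7,1.378,38.610,0.246,17,25,32,39,45,51,56,TRUE
table36,la_maxvol_bsa,male,age_years,8,1.378,40.291,0.229,20,27,34,40,46,52,57,TRUE
table36,la_maxvol_bsa,male,age_years,9,1.378,41.762,0.212,22,29,36,42,48,53,58,TRUE
table36,la_maxvol_bsa,male,age_years,10,1.378,43.375,0.197,25,31,38,43,49,54,59,TRUE
table36,la_maxvol_bsa,male,age_years,11,1.378,45.120,0.183,27,34,39,45,51,56,61,TRUE
table36,la_maxvol_bsa,male,age_years,12,1.378,46.671,0.171,29,35,41,47,52,57,62,TRUE
table36,la_maxvol_bsa,male,age_years,13,1.378,47.784,0.161,31,37,43,48,53,58,62,TRUE
table36,la_maxvol_bsa,male,age_years,14,1.378,48.331,0.152,33,38,43,48,53,58,62,TRUE
table36,la_maxvol_bsa,male,age_years,15,1.378,48.581,0.142,34,39,44,49,53,57,62,TRUE
table36,la_maxvol_bsa,male,age_years,16,1.378,49.112,0.131,36,40,45,49,53,57,61,TRUE
table36,la_maxvol_bsa,male,age_years,17,1.378,50.353,0.120,38,42,46,50,54,58,62,TRUE
table36,la_maxvol_bsa,male,age_years,18,1.378,52.583,0.111,40,45,49,53,56,60,64,TRUE
table36,la_maxvol_bsa,male,age_years,19,1.378,55.860,0.103,44,48,52,56,60,63,67,TRUE
table36,la_maxvol_bsa,male,age_years,20,1.378,59.928,0.097,48,52,56,60,64,67,71,TRUE
table36,la_maxvol_bsa,female,age_years,4,-1.100,37.566,0.248,22,27,31,34,38,41,44,FALSE
table36,la_maxvol_bsa,female,age_years,5,-0.956,38.333,0.242,23,28,32,36,40,43,46,FALSE
table36,la_maxvol_bsa,female,age_years,6,-0.717,39.568,0.234,25,30,34,39,42,46,50,FALSE
table36,la_maxvol_bsa,female,age_years,7,-0.478,40.739,0.225,26,32,36,41,45,49,53,FALSE
table36,la_maxvol_bsa,female,age_years,8,-0.239,41.934,0.217,28,33,38,43,47,51,55,FALSE
table36,la_maxvol_bsa,female,age_years,9,0.000,43.072,0.208,28,34,39,44,48,52,56,FALSE
table36,la_maxvol_bsa,female,age_years,10,0.239,43.953,0.199,28,34,39,44,48,52,56,FALSE
table36,la_maxvol_bsa,female,age_years,11,0.478,44.548,0.191,29,34,39,44,48,53,57,FALSE
table36,la_maxvol_bsa,female,age_years,12,0.717,45.080,0.182,29,35,40,45,49,53,58,FALSE
table36,la_maxvol_bsa,female,age_years,13,0.956,45.636,0.173,30,35,41,45,50,54,59,FALSE
table36,la_maxvol_bsa,female,age_years,14,1.195,46.118,0.165,30,36,41,46,51,56,60,FALSE
table36,la_maxvol_bsa,female,age_years,15,1.434,46.070,0.156,30,36,42,47,51,56,60,FALSE
table36,la_maxvol_bsa,female,age_years,16,1.673,45.343,0.148,30,35,41,45,50,55,59,FALSE
table36,la_maxvol_bsa,female,age_years,17,1.912,44.258,0.139,29,34,39,44,48,53,57,FALSE
table36,la_maxvol_bsa,female,age_years,18,2.151,43.116,0.130,27,33,38,42,47,51,55,FALSE
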