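table_id,parameter_id,sex,covariate,cov_value,c05,c10,c25,c50,c75,c90,c95
table37,la_maxvol,male,bsa_m2,0.8,16,17,19,22,26,29,31
table37,la_maxvol,male,bsa_m2,0.9,17,18,21,25,29,32,35
table37,la_maxvol,male,bsa_m2,1.0,18,20,23,27,32,36,39
table37,la_maxvol,male,bsa_m2,1.1,19,21,25,30,36,41,44
table37,la_maxvol,male,bsa_m2,1.2,21,23,28,33,40,46,49
table37,la_maxvol,male,bsa_m2,1.3,22,25,30,37,44,51,55
table37,la_maxvol,male,bsa_m2,1.4,24,28,34,41,49,56,61
table37,la_maxvol,male,bsa_m2,1.5,27,30,37,45,54,62,67
table37,la_maxvol,male,bsa_m2,1.6,30,34,41,50,59,68,74
table37,la_maxvol,male,bsa_m2,1.7,33,38,46,55,65,75,80
table37,la_maxvol,male,bsa_m2,1.8,38,43,51,61,71,81,87
table37,la_maxvol,male,bsa_m2,1.9,44,49,57,67,78,88,94
table37,la_maxvol,male,bsa_m2,2.0,50,56,64,75,85,95,101
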