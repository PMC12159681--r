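table_id,parameter_id,sex,covariate,cov_value,c05,c10,c25,c50,c75,c90,c95
table23,lvedv,male,height_cm,110,45,47,50,54,59,64,68
table23,lvesv,male,height_cm,110,14,14,16,18,21,24,26
table23,lvsv,male,height_cm,110,27,29,33,37,41,45,48
table23,lvedv,male,height_cm,120,52,55,59,64,70,76,80
table23,lvesv,male,height_cm,120,16,17,19,22,25,29,31
table23,lvsv,male,height_cm,120,31,34,38,42,48,52,55
table23,lvedv,male,height_cm,130,61,64,69,75,82,90,95
table23,lvesv,male,height_cm,130,19,21,23,26,30,35,38
table23,lvsv,male,height_cm,130,36,39,44,49,55,61,64
table23,lvedv,male,height_cm,140,71,75,81,89,97,107,112
table23,lvesv,male,height_cm,140,23,25,28,32,37,42,46
table23,lvsv,male,height_cm,140,42,45,51,57,64,70,74
table23,lvedv,male,height_cm,150,82,87,95,105,115,126,133
table23,lvesv,male,height_cm,150,27,29,33,39,45,51,55
table23,lvsv,male,height_cm,150,49,52,59,66,74,81,86
table23,lvedv,male,height_cm,160,95,101,111,123,137,149,157
table23,lvesv,male,height_cm,160,32,35,40,47,54,62,67
table23,lvsv,male,height_cm,160,57,61,68,76,85,94,99
table23,lvedv,male,height_cm,170,110,118,130,146,162,177,186
table23,lvesv,male,height_cm,170,38,42,48,56,66,75,81
table23,lvsv,male,height_cm,170,66,70,78,88,98,108,114
table23,lvedv,male,height_cm,180,127,136,153,172,191,209,220
table23,lvesv,male,height_cm,180,44,49,58,68,79,90,98
table23,lvsv,male,height_cm,180,76,82,91,102,114,125,132
table23,lvedv,male,height_cm,190,145,158,179,203,226,247,260
table23,lvesv,male,height_cm,190,52,58,69,82,96,110,118
table23,lvsv,male,height_cm,190,88,95,105,118,132,145,153
table23,lvedv,male,height_cm,200,164,181,209,239,267,292,306
table23,lvesv,male,height_cm,200,60,68,83,99,116,132,142
table23,lvsv,male,height_cm,200,102,109,122,136,152,167,176
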