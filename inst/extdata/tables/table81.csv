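table_id,parameter_id,sex,covariate,cov_value,L,M,S,c03,c10,c25,c50,c75,c90,c97,centiles_consistent
table81,aorta_pwv,male,age_years,0,1.4844,3.4147,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,0,-1.5196,2.7808,0.1468,,,,,,,,NA
table81,aorta_pwv,male,age_years,1,1.4844,3.4367,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,1,-1.5196,2.8144,0.1469,,,,,,,,NA
table81,aorta_pwv,male,age_years,2,1.4844,3.4587,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,2,-1.5196,2.8481,0.1469,,,,,,,,NA
table81,aorta_pwv,male,age_years,3,1.4844,3.4808,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,3,-1.5196,2.8817,0.1469,,,,,,,,NA
table81,aorta_pwv,male,age_years,4,1.4844,3.5028,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,4,-1.5196,2.9154,0.1470,,,,,,,,NA
table81,aorta_pwv,male,age_years,5,1.4844,3.5248,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,5,-1.5196,2.9490,0.1470,,,,,,,,NA
table81,aorta_pwv,male,age_years,6,1.4844,3.5469,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,6,-1.5196,2.9827,0.1470,,,,,,,,NA
table81,aorta_pwv,male,age_years,7,1.4844,3.5689,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,7,-1.5196,3.0163,0.1470,,,,,,,,NA
table81,aorta_pwv,male,age_years,8,1.4844,3.5909,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,8,-1.5196,3.0499,0.1471,,,,,,,,NA
table81,aorta_pwv,male,age_years,9,1.4844,3.6129,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,9,-1.5196,3.0836,0.1471,,,,,,,,NA
table81,aorta_pwv,male,age_years,10,1.4844,3.6350,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,10,-1.5196,3.1172,0.1471,,,,,,,,NA
table81,aorta_pwv,male,age_years,11,1.4844,3.6570,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,11,-1.5196,3.1509,0.1471,,,,,,,,NA
table81,aorta_pwv,male,age_years,12,1.4844,3.6790,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,12,-1.5196,3.1845,0.1472,,,,,,,,NA
table81,aorta_pwv,male,age_years,13,1.4844,3.7011,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,13,-1.5196,3.2182,0.1472,,,,,,,,NA
table81,aorta_pwv,male,age_years,14,1.4844,3.7231,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,14,-1.5196,3.2518,0.1472,,,,,,,,NA
table81,aorta_pwv,male,age_years,15,1.4844,3.7451,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,15,-1.5196,3.2855,0.1473,,,,,,,,NA
table81,aorta_pwv,male,age_years,16,1.4844,3.7672,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,16,-1.5196,3.3192,0.1473,,,,,,,,NA
table81,aorta_pwv,male,age_years,17,1.4844,3.7892,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,17,-1.5196,3.3528,0.1473,,,,,,,,NA
table81,aorta_pwv,male,age_years,18,1.4844,3.8112,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,18,-1.5196,3.3865,0.1473,,,,,,,,NA
table81,aorta_pwv,male,age_years,19,1.4844,3.8333,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,19,-1.5196,3.4201,0.1474,,,,,,,,NA
table81,aorta_pwv,male,age_years,20,1.4844,3.8553,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,20,-1.5196,3.4538,0.1474,,,,,,,,NA
table81,aorta_pwv,male,age_years,21,1.4844,3.8773,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,21,-1.5196,3.4875,0.1474,,,,,,,,NA
table81,aorta_pwv,male,age_years,22,1.4844,3.8994,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,22,-1.5196,3.5211,0.1475,,,,,,,,NA
table81,aorta_pwv,male,age_years,23,1.4844,3.9214,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,23,-1.5196,3.5548,0.1475,,,,,,,,NA
table81,aorta_pwv,male,age_years,24,1.4844,3.9434,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,24,-1.5196,3.5885,0.1475,,,,,,,,NA
table81,aorta_pwv,male,age_years,25,1.4844,3.9655,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,25,-1.5196,3.6221,0.1476,,,,,,,,NA
table81,aorta_pwv,male,age_years,26,1.4844,3.9875,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,26,-1.5196,3.6558,0.1476,,,,,,,,NA
table81,aorta_pwv,male,age_years,27,1.4844,4.0096,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,27,-1.5196,3.6895,0.1476,,,,,,,,NA
table81,aorta_pwv,male,age_years,28,1.4844,4.0316,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,28,-1.5196,3.7231,0.1476,,,,,,,,NA
table81,aorta_pwv,male,age_years,29,1.4844,4.0536,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,29,-1.5196,3.7568,0.1477,,,,,,,,NA
table81,aorta_pwv,male,age_years,30,1.4844,4.0757,0.2122,,,,,,,,NA
table81,aorta_pwv,female,age_years,30,-1.5196,3.7905,0.1477,,,,,,,,NA
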