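table_id,parameter_id,site,sex,age_lo,age_hi,transform,intercept,slope,sd_residuals,units,precision
table86,pa_diam,Main pulmonary artery (axial),all,0,18,sqrt_bsa,4.85,13.43,2.72,mm,1
table86,pa_diam,Main pulmonary artery (sagittal),all,0,18,sqrt_bsa,1.04,17.07,2.01,mm,1
table86,pa_diam,Proximal right pulmonary artery (axial),all,0,18,sqrt_bsa,2.63,9.19,1.65,mm,1
table86,pa_diam,Distal right pulmonary artery (axial),all,0,18,sqrt_bsa,3.9,6.25,1.49,mm,1
table86,pa_diam,Proximal right pulmonary artery (RAO),all,0,18,sqrt_bsa,-0.69,14.3,1.76,mm,1
table86,pa_diam,Distal right pulmonary artery (RAO),all,0,18,sqrt_bsa,-1.08,14.62,1.6,mm,1
table86,pa_diam,Proximal left pulmonary artery (axial),all,0,18,sqrt_bsa,1.7,11.27,1.37,mm,1
table86,pa_diam,Distal left pulmonary artery (axial),all,0,18,sqrt_bsa,-0.1,11.89,1.51,mm,1
table86,pa_diam,Proximal left pulmonary artery (LAO),all,0,18,sqrt_bsa,-2.13,16.82,1.88,mm,1
table86,pa_diam,Distal left pulmonary artery (LAO),all,0,18,sqrt_bsa,-2.08,13.64,1.5,mm,1
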