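table_id,parameter_id,site,sex,age_lo,age_hi,transform,intercept,slope,sd_residuals,units,precision
table87,pa_area_mpa,Main pulmonary artery,all,0,18,bsa,-0.288,3.386,,cm^2,2
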