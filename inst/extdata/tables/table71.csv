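table_id,parameter_id,site,sex,age_lo,age_hi,transform,intercept,slope,sd_residuals,units,precision
table71,aorta_diam,Aortic sinus,all,0,18,sqrt_bsa,0.57,19.37,2.38,mm,1
table71,aorta_diam,Sinotubular junction,all,0,18,sqrt_bsa,-0.03,16.91,1.92,mm,1
table71,aorta_diam,Ascending aorta,all,0,18,sqrt_bsa,-1.33,18.6,1.99,mm,1
table71,aorta_diam,Proximal to the origin of the brachiocephalic artery,all,0,18,sqrt_bsa,-3.38,20.07,1.69,mm,1
table71,aorta_diam,First transverse segment,all,0,18,sqrt_bsa,-3.52,18.66,1.63,mm,1
table71,aorta_diam,Second transverse segment,all,0,18,sqrt_bsa,-2.63,16.5,1.31,mm,1
table71,aorta_diam,Isthmic region,all,0,18,sqrt_bsa,-3.37,16.52,1.46,mm,1
table71,aorta_diam,Descending aorta,all,0,18,sqrt_bsa,-1.12,14.42,1.64,mm,1
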