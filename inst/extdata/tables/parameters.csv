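id,name,units,indexing,plane
lvedv,LV end-diastolic volume,mL,absolute,SAX
lvedv_bsa,LV end-diastolic volume / BSA,mL/m^2,per_bsa,SAX
lvesv,LV end-systolic volume,mL,absolute,SAX
lvesv_bsa,LV end-systolic volume / BSA,mL/m^2,per_bsa,SAX
lvsv,LV stroke volume,mL,absolute,SAX
lvsv_bsa,LV stroke volume / BSA,mL/m^2,per_bsa,SAX
lvef,LV ejection fraction,%,absolute,SAX
lvm,LV mass,g,absolute,SAX
lvm_bsa,LV mass / BSA,g/m^2,per_bsa,SAX
lvco,LV cardiac output,L/min,absolute,SAX
lvci,LV cardiac index,L/min/m^2,per_bsa,SAX
lvm_lvedv,LV mass-to-volume ratio,g/mL,absolute,SAX
rvedv,RV end-diastolic volume,mL,absolute,SAX
rvedv_bsa,RV end-diastolic volume / BSA,mL/m^2,per_bsa,SAX
rvesv,RV end-systolic volume,mL,absolute,SAX
rvesv_bsa,RV end-systolic volume / BSA,mL/m^2,per_bsa,SAX
rvm,RV mass,g,absolute,SAX
rvm_bsa,RV mass / BSA,g/m^2,per_bsa,SAX
rvef,RV ejection fraction,%,absolute,SAX
la_maxvol_bsa,Maximal LA volume / BSA,mL/m^2,per_bsa,axial stack
la_maxvol,Maximal LA volume,mL,absolute,2ch+4ch
ra_maxvol_bsa,Maximal RA volume / BSA,mL/m^2,per_bsa,axial stack
mpa_diam_sys,Main pulmonary artery systolic diameter,mm,absolute,cross-sectional
mpa_diam_dia,Main pulmonary artery diastolic diameter,mm,absolute,cross-sectional
mpa_area_sys,Main pulmonary artery systolic area,cm^2,absolute,cross-sectional
mpa_area_dia,Main pulmonary artery diastolic area,cm^2,absolute,cross-sectional
mpa_distension,Main pulmonary artery distension,%,absolute,cross-sectional
t1_native_myo,Native myocardial T1 relaxation time,ms,absolute,SAX mid septum
t2_myo,Myocardial T2 relaxation time,ms,absolute,SAX mid septum
aorta_dist_asc,Ascending aortic distensibility,10^-3 mmHg^-1,absolute,cross-sectional
aorta_pwv,Aortic arch pulse wave velocity,m/s,absolute,arch
aorta_diam,Thoracic aortic diameter,mm,absolute,MRA
pa_diam,Pulmonary artery diameter,mm,absolute,MRA
pa_area_mpa,Main pulmonary artery area,cm^2,absolute,phase contrast
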