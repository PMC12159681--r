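table_id,parameter_id,sex,covariate,cov_value,L,M,S,c03,c10,c25,c50,c75,c90,c97,centiles_consistent
table80,aorta_dist_asc,male,age_years,0,-0.1879,12.3602,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,0,-0.0721,12.7303,0.2388,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,1,-0.1879,11.9220,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,1,-0.0721,12.5028,0.2396,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,2,-0.1879,11.4838,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,2,-0.0721,12.2753,0.2403,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,3,-0.1879,11.0456,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,3,-0.0721,12.0477,0.2411,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,4,-0.1879,10.6075,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,4,-0.0721,11.8176,0.2419,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,5,-0.1879,10.1700,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,5,-0.0721,11.5817,0.2427,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,6,-0.1879,9.7343,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,6,-0.0721,11.3421,0.2435,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,7,-0.1879,9.2990,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,7,-0.0721,11.1121,0.2443,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,8,-0.1879,8.8602,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,8,-0.0721,10.9051,0.2451,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,9,-0.1879,8.4151,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,9,-0.0721,10.7290,0.2459,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,10,-0.1879,7.9776,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,10,-0.0721,10.5679,0.2467,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,11,-0.1879,7.5683,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,11,-0.0721,10.3851,0.2474,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,12,-0.1879,7.2051,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,12,-0.0721,10.1582,0.2482,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,13,-0.1879,6.9030,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,13,-0.0721,9.8884,0.2490,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,14,-0.1879,6.6697,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,14,-0.0721,9.5911,0.2498,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,15,-0.1879,6.5089,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,15,-0.0721,9.2905,0.2506,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,16,-0.1879,6.4138,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,16,-0.0721,9.0033,0.2514,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,17,-0.1879,6.3729,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,17,-0.0721,8.7345,0.2522,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,18,-0.1879,6.3745,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,18,-0.0721,8.4850,0.2529,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,19,-0.1879,6.4062,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,19,-0.0721,8.2574,0.2537,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,20,-0.1879,6.4551,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,20,-0.0721,8.0546,0.2545,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,21,-0.1879,6.5111,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,21,-0.0721,7.8749,0.2553,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,22,-0.1879,6.5646,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,22,-0.0721,7.7106,0.2561,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,23,-0.1879,6.6062,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,23,-0.0721,7.5479,0.2569,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,24,-0.1879,6.6277,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,24,-0.0721,7.3842,0.2577,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,25,-0.1879,6.6242,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,25,-0.0721,7.2113,0.2584,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,26,-0.1879,6.5975,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,26,-0.0721,7.0343,0.2592,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,27,-0.1879,6.5577,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,27,-0.0721,6.8647,0.2600,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,28,-0.1879,6.5116,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,28,-0.0721,6.6951,0.2608,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,29,-0.1879,6.4643,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,29,-0.0721,6.5250,0.2616,,,,,,,,NA
table80,aorta_dist_asc,male,age_years,30,-0.1879,6.4170,0.3680,,,,,,,,NA
table80,aorta_dist_asc,female,age_years,30,-0.0721,6.3550,0.2624,,,,,,,,NA
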