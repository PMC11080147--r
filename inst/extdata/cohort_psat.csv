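id,deploy_date,popup_date,programmed_d,duration_d,sampling_s,temp_min_c,temp_max_c,max_depth_m,track_distance_km,light_days,light_pct,sst_days,sst_pct,pdt_days,pdt_pct,depth_days,depth_pct,obs_likelihoods
01,2018-09-20,2019-01-18,120,120,3,14.3,24.3,125,645,89,74,0,0,36,30,75,62,H B
02,2018-09-20,2019-03-19,180,180,5,14.3,24.9,82,438,51,28,1,1,28,15,76,42,S O B
03,2018-09-20,2019-03-05,180,166,5,13.3,24.8,90,879,145,87,20,12,164,98,167,100,L H B
04,2018-09-20,2018-10-18,180,28,5,14.2,24.2,76,172,26,90,1,3,27,93,29,100,L S B
05,2018-09-20,2019-01-08,120,110,3,14.5,24.8,64,499,96,86,4,4,93,84,111,100,S O B
06,2018-09-20,2019-01-18,120,120,3,14.5,24.7,90,418,72,60,2,2,30,25,84,69,S O B
07,2019-07-09,NA,300,NA,3,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
08,2019-07-09,2020-05-04,300,300,3,13.1,24.8,125,2366,251,83,53,18,285,95,301,100,L S B
17,2019-09-27,2020-01-29,300,124,3,13.7,20.5,80,917,50,40,12,10,71,57,101,81,L S B
18,2019-09-27,2019-12-19,300,83,3,13.3,21.8,113,350,71,85,9,11,78,93,84,100,L O B
19,2019-09-27,NA,300,NA,3,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
20,2019-09-27,2020-07-23,300,300,3,13.6,23.4,121,1464,255,85,39,13,294,98,301,100,S O B
21,2019-09-27,2020-07-23,300,300,3,13.5,22.7,88,833,34,11,14,5,22,7,69,23,S O B
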