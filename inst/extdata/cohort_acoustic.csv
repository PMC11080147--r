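id,transmitter,total_length_cm,tagging_site,release_date,last_detection,n_detections,n_receivers,detection_span_d,days_detected,residency_index
01,A69-1602-23797,131,APPA,2018-09-20,2019-11-23,1757,9,430,28,0.07
02,A69-1602-23798,128,APPA,2018-09-20,2021-11-22,2891,3,1160,15,0.01
03,A69-1602-23800,131,APPA,2018-09-20,2021-09-30,2240,51,1107,33,0.03
04,A69-1602-23799,132,APPA,2018-09-20,NA,NA,NA,NA,NA,NA
05,A69-1602-23802,142,APPA,2018-09-20,2022-01-04,4093,35,1203,83,0.07
06,A69-1602-23801,127,APPA,2018-09-20,2020-08-23,3715,60,704,70,0.10
07,A69-1602-23836,126,APPA,2019-07-09,2022-07-02,977,12,1090,27,0.02
08,A69-1602-23834,122,APPA,2019-07-09,2020-07-08,515,22,366,14,0.04
09,A69-1602-23835,135,APPA,2019-07-09,2019-11-15,887,34,130,24,0.18
10,A69-1602-23833,124,APPA,2019-07-09,2022-07-06,862,28,1094,32,0.03
11,A69-1602-23799,125,APPA,2019-07-10,2020-07-23,323,9,380,10,0.03
12,A69-1602-23803,134,APPA,2019-07-10,2020-02-18,314,15,224,10,0.04
13,A69-1602-23804,134,APPA,2019-07-10,2022-07-12,2629,41,1099,27,0.02
14,A69-1602-23805,134,APPA,2019-07-10,2022-10-12,398,3,1191,30,0.03
15,A69-1602-23806,128,APPA,2019-07-10,2019-08-27,236,4,49,9,0.18
16,A69-1602-23827,100,Tejo,2019-07-22,2021-08-27,13314,2,768,287,0.37
17,A69-1602-23828,143,APPA,2019-09-27,2019-10-29,54,5,33,2,0.06
18,A69-1602-23829,131,APPA,2019-09-27,2021-07-16,186,9,659,13,0.02
19,A69-1602-23831,112,APPA,2019-09-27,2022-06-09,238,3,987,4,0.00
20,A69-1602-23832,126,APPA,2019-09-27,2021-07-16,110,4,659,7,0.01
21,A69-1602-23830,130,APPA,2019-09-27,2020-07-18,143,2,296,3,0.01
22,A69-1602-23808,70,Tejo,2020-05-28,2021-12-18,46805,12,570,443,0.78
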