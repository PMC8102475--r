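animal_id,weight_kg,icg_dose_mg,timepoint_min,assessment,ne_dose,systolic,diastolic,hr,lactate
pig1,33.0,3.3,0,1,0,85,48,97,0.8
pig1,33.0,3.3,10,NA,0,66,38,92,NA
pig1,33.0,3.3,25,2,0.1,89,60,95,Low
pig1,33.0,3.3,35,NA,0.1,94,51,98,NA
pig1,33.0,3.3,50,3,0.5,155,97,101,0.6
pig1,33.0,3.3,60,NA,0.5,128,68,92,NA
pig1,33.0,3.3,75,4,1.0,127,65,92,Low
pig1,33.0,3.3,85,5,1.0,48,32,125,Low
pig2,42.1,4.2,0,1,0,53,38,90,Low
pig2,42.1,4.2,10,NA,0,57,41,89,NA
pig2,42.1,4.2,25,2,0.1,76,58,76,Low
pig2,42.1,4.2,35,NA,0.1,65,50,79,NA
pig2,42.1,4.2,50,3,0.5,77,52,95,Low
pig2,42.1,4.2,60,NA,0.5,49,38,103,NA
pig2,42.1,4.2,75,4,1.0,125,74,146,Low
pig2,42.1,4.2,85,5,1.0,32,23,113,Low
pig3,41.4,4.1,0,1,0,58,30,84,0.6
pig3,41.4,4.1,10,NA,0,61,32,88,NA
pig3,41.4,4.1,25,2,0.1,91,48,88,Low
pig3,41.4,4.1,35,NA,0.1,78,41,90,NA
pig3,41.4,4.1,50,3,0.5,130,60,136,Low
pig3,41.4,4.1,60,NA,0.5,101,47,125,NA
pig3,41.4,4.1,75,4,1.0,128,62,143,Low
pig3,41.4,4.1,85,5,1.0,30,20,116,Low
pig4,41.0,4.1,0,1,0,60,35,63,1.1
pig4,41.0,4.1,10,NA,0,55,33,60,NA
pig4,41.0,4.1,25,2,0.1,93,57,82,1.3
pig4,41.0,4.1,35,NA,0.1,88,55,82,NA
pig4,41.0,4.1,50,3,0.5,134,102,105,Low
pig4,41.0,4.1,60,NA,0.5,124,73,103,NA
pig4,41.0,4.1,75,4,1.0,132,83,120,0.6
pig4,41.0,4.1,85,5,1.0,45,25,76,Low
pig5,44.0,4.4,0,1,0,52,29,95,Low
pig5,44.0,4.4,10,NA,0,35,27,83,NA
pig5,44.0,4.4,25,2,0.1,70,38,98,1.0
pig5,44.0,4.4,35,NA,0.1,64,33,98,NA
pig5,44.0,4.4,50,3,0.5,89,46,107,0.8
pig5,44.0,4.4,60,NA,0.5,80,42,125,NA
pig5,44.0,4.4,75,4,1.0,81,45,142,0.6
pig5,44.0,4.4,85,5,1.0,41,24,110,0.7
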