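variable,level,cases,mastectomies
total,all,26017,8802
total_eligible,all,20229,5829
stage,0,5451,1439
stage,I,10673,2988
stage,II,6353,2796
stage,III,1940,1306
stage,IV,1097,188
stage,NA,503,85
size_group,0.0-0.9,5236,1271
size_group,1.0-1.9,8172,2407
size_group,2.0-2.9,4308,1655
size_group,3.0-3.9,2033,911
size_group,4.0-4.9,1100,563
size_group,5.0+,2043,1280
size_group,NA,3125,715
nodes_group,0,14018,5177
nodes_group,1,2331,1043
nodes_group,2+,2940,1760
nodes_group,NA,6728,822
grade,I,5556,1488
grade,II,10580,3693
grade,III,7683,3122
grade,IV,161,59
grade,NA,2037,440
age_group,40-49,4392,1956
age_group,50-64,10284,3519
age_group,65-84,10062,3003
age_group,85+,1279,324
histology,dcis,4666,NA
histology,in_situ_total,5451,NA
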