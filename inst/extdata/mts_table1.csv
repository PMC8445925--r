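record_id,limb,length_cm,width_cm,toe_impressions,trackway_id,overstepped,x_m,y_m,notes,age_class_block,esh_m_cm,ebm_m_kg,ea_m_yr,esh_f_cm,ebm_f_kg,ea_f_yr
PAT/MTS/005,P,9.6,7.3,,,FALSE,,,,calf,66,70,<1,56,43,<1
PAT/MTS/012x,M,9.6,8.1,,,FALSE,,,,calf,66,70,<1,56,43,<1
PAT/MTS/016,M,10,8.2,,,FALSE,,,,calf,69,79,<1,58,48,<1
PAT/MTS/011a,M,10.8,11.7,5,,FALSE,,,,calf,73,93,<1,62,58,<1
PAT/MTS/012j,P,11.3,9.4,,,FALSE,,,,calf,76,105,<1,65,67,<1
PAT/MTS/008d,M,13.8,13.7,4,,FALSE,,,,calf,91,177,<1,78,113,<1
PAT/MTS/012a,P,14.1,10.8,2-3,,FALSE,,,,calf,92,182,<1,80,122,<1
PAT/MTS/011f,M,14.2,11.5,,,FALSE,,,,calf,92,182,<1,80,122,<1
PAT/MTS/007a,P,14.6,10.5,3,,FALSE,,,,calf,95,200,<1,83,135,<1
PAT/MTS/010f,M,15,17,,,FALSE,,,,calf,98,219,<1,85,145,<1
PAT/MTS/014,P,15.5,12,3,,FALSE,,,,calf,100,232,<1,88,160,<1
PAT/MTS/003k,M,15.7,22.7,,,FALSE,,,,calf,102,246,<1,89,166,<1
PAT/MTS/015x,M,16,17,,,FALSE,,,,calf,104,260,<1,92,182,<1
PAT/MTS/012c,P,16.9,11.4,,,FALSE,,,,calf,109,298,<1,95,200,<1
PAT/MTS/012b,P,17.7,10.5,1,,FALSE,,,,calf,113,331,1,100,232,1
PAT/MTS/009,M,19.4,17,,,FALSE,,,ambiguous stray digit 3 after ages in source,juvenile,123,424,2,109,298,1
PAT/MTS/011e,P,20.6,15.3,3,,FALSE,,,,juvenile,130,497,3,116,357,2
PAT/MTS/003g,M,21.8,23.8,,,FALSE,,,,juvenile,137,579,2,122,414,2
PAT/MTS/010b,P,22,17,,,FALSE,,,,juvenile,138,592,3,123,424,3
PAT/MTS/008e,P,22.6,15.1,3-4,,FALSE,,,,juvenile,142,643,3,127,465,2
PAT/MTS/003i,M,23.4,23.1,,,FALSE,,,,juvenile,146,697,3,131,509,3
PAT/MTS/003a,M,26.5,31,,,FALSE,,,,juvenile,164,976,6,148,725,4
PAT/MTS/013,P,29.5,24,,,FALSE,,,,juvenile,182,1321,7,164,976,7
PAT/MTS/003p,M,28.9,26.6,,,FALSE,,,,adolescent,178,1238,8,161,925,6
PAT/MTS/005,M,30,31,,,FALSE,,,,adolescent,185,1385,8,167,1029,7
PAT/MTS/001,M,30.9,33,5,,FALSE,,,,adolescent,190,1497,11,172,1121,8
PAT/MTS/015a,M,31.1,32,,,FALSE,,,,adolescent,,,,173,1140,8
PAT/MTS/003d,P,33.3,24.5,,,FALSE,,,,adolescent,204,1840,11,185,1385,9
PAT/MTS/003b,P,37.2,27.8,,,FALSE,,,,adolescent,227,2509,14,206,1893,13
PAT/MTS/003j,P,40.1,21.8,,,FALSE,,,,adult,243,3057,17,222,1121,21
PAT/MTS/003c,P,40.7,29,,,FALSE,,,,adult,247,3026,17,226,2477,26
PAT/MTS/003f,P,45.8,30.7,,,FALSE,,,,adult,277,4471,33,,,>40
PAT/MTS/004b,P,51,36.5,3,,FALSE,,,,adult,307,6027,<60,,,
PAT/MTS/003q,P,54.5,31.6,,,FALSE,,,,adult,325,7111,<70,,,
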