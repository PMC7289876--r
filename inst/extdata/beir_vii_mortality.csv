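sex,age_anchor,site,n_per_100k_at_100mgy,source_label
male,0,all_solid,1099,BEIR-VII-12D2
male,5,all_solid,852,BEIR-VII-12D2
male,10,all_solid,712,BEIR-VII-12D2
male,15,all_solid,603,BEIR-VII-12D2
male,20,all_solid,511,BEIR-VII-12D2
male,30,all_solid,381,BEIR-VII-12D2
male,40,all_solid,377,BEIR-VII-12D2
male,50,all_solid,360,BEIR-VII-12D2
male,60,all_solid,319,BEIR-VII-12D2
male,70,all_solid,250,BEIR-VII-12D2
male,80,all_solid,153,BEIR-VII-12D2
female,0,all_solid,1770,BEIR-VII-12D2
female,5,all_solid,1347,BEIR-VII-12D2
female,10,all_solid,1104,BEIR-VII-12D2
female,15,all_solid,914,BEIR-VII-12D2
female,20,all_solid,762,BEIR-VII-12D2
female,30,all_solid,542,BEIR-VII-12D2
female,40,all_solid,507,BEIR-VII-12D2
female,50,all_solid,469,BEIR-VII-12D2
female,60,all_solid,409,BEIR-VII-12D2
female,70,all_solid,317,BEIR-VII-12D2
female,80,all_solid,190,BEIR-VII-12D2
male,0,leukemia,71,BEIR-VII-12D2
male,5,leukemia,71,BEIR-VII-12D2
male,10,leukemia,71,BEIR-VII-12D2
male,15,leukemia,70,BEIR-VII-12D2
male,20,leukemia,67,BEIR-VII-12D2
male,30,leukemia,64,BEIR-VII-12D2
male,40,leukemia,67,BEIR-VII-12D2
male,50,leukemia,71,BEIR-VII-12D2
male,60,leukemia,73,BEIR-VII-12D2
male,70,leukemia,63,BEIR-VII-12D2
male,80,leukemia,38,BEIR-VII-12D2
female,0,leukemia,53,BEIR-VII-12D2
female,5,leukemia,52,BEIR-VII-12D2
female,10,leukemia,53,BEIR-VII-12D2
female,15,leukemia,52,BEIR-VII-12D2
female,20,leukemia,51,BEIR-VII-12D2
female,30,leukemia,51,BEIR-VII-12D2
female,40,leukemia,52,BEIR-VII-12D2
female,50,leukemia,54,BEIR-VII-12D2
female,60,leukemia,55,BEIR-VII-12D2
female,70,leukemia,47,BEIR-VII-12D2
female,80,leukemia,27,BEIR-VII-12D2
male,0,stomach,41,BEIR-VII-12D2
male,5,stomach,34,BEIR-VII-12D2
male,10,stomach,30,BEIR-VII-12D2
male,15,stomach,25,BEIR-VII-12D2
male,20,stomach,21,BEIR-VII-12D2
male,30,stomach,16,BEIR-VII-12D2
male,40,stomach,15,BEIR-VII-12D2
male,50,stomach,13,BEIR-VII-12D2
male,60,stomach,11,BEIR-VII-12D2
male,70,stomach,8,BEIR-VII-12D2
male,80,stomach,4,BEIR-VII-12D2
female,0,stomach,57,BEIR-VII-12D2
female,5,stomach,48,BEIR-VII-12D2
female,10,stomach,41,BEIR-VII-12D2
female,15,stomach,34,BEIR-VII-12D2
female,20,stomach,29,BEIR-VII-12D2
female,30,stomach,21,BEIR-VII-12D2
female,40,stomach,20,BEIR-VII-12D2
female,50,stomach,19,BEIR-VII-12D2
female,60,stomach,16,BEIR-VII-12D2
female,70,stomach,13,BEIR-VII-12D2
female,80,stomach,8,BEIR-VII-12D2
male,0,colon,163,BEIR-VII-12D2
male,5,colon,139,BEIR-VII-12D2
male,10,colon,117,BEIR-VII-12D2
male,15,colon,99,BEIR-VII-12D2
male,20,colon,84,BEIR-VII-12D2
male,30,colon,61,BEIR-VII-12D2
male,40,colon,60,BEIR-VII-12D2
male,50,colon,57,BEIR-VII-12D2
male,60,colon,49,BEIR-VII-12D2
male,70,colon,36,BEIR-VII-12D2
male,80,colon,21,BEIR-VII-12D2
female,0,colon,102,BEIR-VII-12D2
female,5,colon,86,BEIR-VII-12D2
female,10,colon,72,BEIR-VII-12D2
female,15,colon,61,BEIR-VII-12D2
female,20,colon,52,BEIR-VII-12D2
female,30,colon,38,BEIR-VII-12D2
female,40,colon,37,BEIR-VII-12D2
female,50,colon,35,BEIR-VII-12D2
female,60,colon,31,BEIR-VII-12D2
female,70,colon,25,BEIR-VII-12D2
female,80,colon,15,BEIR-VII-12D2
male,0,liver,44,BEIR-VII-12D2
male,5,liver,37,BEIR-VII-12D2
male,10,liver,31,BEIR-VII-12D2
male,15,liver,27,BEIR-VII-12D2
male,20,liver,23,BEIR-VII-12D2
male,30,liver,16,BEIR-VII-12D2
male,40,liver,16,BEIR-VII-12D2
male,50,liver,14,BEIR-VII-12D2
male,60,liver,12,BEIR-VII-12D2
male,70,liver,8,BEIR-VII-12D2
male,80,liver,4,BEIR-VII-12D2
female,0,liver,24,BEIR-VII-12D2
female,5,liver,20,BEIR-VII-12D2
female,10,liver,17,BEIR-VII-12D2
female,15,liver,14,BEIR-VII-12D2
female,20,liver,12,BEIR-VII-12D2
female,30,liver,9,BEIR-VII-12D2
female,40,liver,8,BEIR-VII-12D2
female,50,liver,8,BEIR-VII-12D2
female,60,liver,7,BEIR-VII-12D2
female,70,liver,5,BEIR-VII-12D2
female,80,liver,3,BEIR-VII-12D2
male,0,lung,318,BEIR-VII-12D2
male,5,lung,264,BEIR-VII-12D2
male,10,lung,219,BEIR-VII-12D2
male,15,lung,182,BEIR-VII-12D2
male,20,lung,151,BEIR-VII-12D2
male,30,lung,107,BEIR-VII-12D2
male,40,lung,107,BEIR-VII-12D2
male,50,lung,104,BEIR-VII-12D2
male,60,lung,93,BEIR-VII-12D2
male,70,lung,71,BEIR-VII-12D2
male,80,lung,42,BEIR-VII-12D2
female,0,lung,643,BEIR-VII-12D2
female,5,lung,534,BEIR-VII-12D2
female,10,lung,442,BEIR-VII-12D2
female,15,lung,367,BEIR-VII-12D2
female,20,lung,305,BEIR-VII-12D2
female,30,lung,212,BEIR-VII-12D2
female,40,lung,213,BEIR-VII-12D2
female,50,lung,212,BEIR-VII-12D2
female,60,lung,201,BEIR-VII-12D2
female,70,lung,160,BEIR-VII-12D2
female,80,lung,97,BEIR-VII-12D2
female,0,breast,274,BEIR-VII-12D2
female,5,breast,214,BEIR-VII-12D2
female,10,breast,167,BEIR-VII-12D2
female,15,breast,130,BEIR-VII-12D2
female,20,breast,101,BEIR-VII-12D2
female,30,breast,61,BEIR-VII-12D2
female,40,breast,35,BEIR-VII-12D2
female,50,breast,19,BEIR-VII-12D2
female,60,breast,9,BEIR-VII-12D2
female,70,breast,5,BEIR-VII-12D2
female,80,breast,2,BEIR-VII-12D2
male,0,prostate,17,BEIR-VII-12D2
male,5,prostate,15,BEIR-VII-12D2
male,10,prostate,12,BEIR-VII-12D2
male,15,prostate,10,BEIR-VII-12D2
male,20,prostate,9,BEIR-VII-12D2
male,30,prostate,7,BEIR-VII-12D2
male,40,prostate,6,BEIR-VII-12D2
male,50,prostate,7,BEIR-VII-12D2
male,60,prostate,7,BEIR-VII-12D2
male,70,prostate,7,BEIR-VII-12D2
male,80,prostate,5,BEIR-VII-12D2
female,0,uterus,11,BEIR-VII-12D2
female,5,uterus,10,BEIR-VII-12D2
female,10,uterus,8,BEIR-VII-12D2
female,15,uterus,7,BEIR-VII-12D2
female,20,uterus,6,BEIR-VII-12D2
female,30,uterus,4,BEIR-VII-12D2
female,40,uterus,4,BEIR-VII-12D2
female,50,uterus,3,BEIR-VII-12D2
female,60,uterus,3,BEIR-VII-12D2
female,70,uterus,2,BEIR-VII-12D2
female,80,uterus,1,BEIR-VII-12D2
female,0,ovary,55,BEIR-VII-12D2
female,5,ovary,47,BEIR-VII-12D2
female,10,ovary,39,BEIR-VII-12D2
female,15,ovary,34,BEIR-VII-12D2
female,20,ovary,28,BEIR-VII-12D2
female,30,ovary,20,BEIR-VII-12D2
female,40,ovary,20,BEIR-VII-12D2
female,50,ovary,18,BEIR-VII-12D2
female,60,ovary,15,BEIR-VII-12D2
female,70,ovary,11,BEIR-VII-12D2
female,80,ovary,5,BEIR-VII-12D2
male,0,bladder,45,BEIR-VII-12D2
male,5,bladder,38,BEIR-VII-12D2
male,10,bladder,32,BEIR-VII-12D2
male,15,bladder,27,BEIR-VII-12D2
male,20,bladder,23,BEIR-VII-12D2
male,30,bladder,17,BEIR-VII-12D2
male,40,bladder,17,BEIR-VII-12D2
male,50,bladder,17,BEIR-VII-12D2
male,60,bladder,17,BEIR-VII-12D2
male,70,bladder,15,BEIR-VII-12D2
male,80,bladder,10,BEIR-VII-12D2
female,0,bladder,59,BEIR-VII-12D2
female,5,bladder,51,BEIR-VII-12D2
female,10,bladder,43,BEIR-VII-12D2
female,15,bladder,36,BEIR-VII-12D2
female,20,bladder,30,BEIR-VII-12D2
female,30,bladder,22,BEIR-VII-12D2
female,40,bladder,22,BEIR-VII-12D2
female,50,bladder,24,BEIR-VII-12D2
female,60,bladder,22,BEIR-VII-12D2
female,70,bladder,19,BEIR-VII-12D2
female,80,bladder,13,BEIR-VII-12D2
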