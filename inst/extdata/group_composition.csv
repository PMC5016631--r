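group_id,n_adult_males,n_adult_females,n_offspring,fis,region_id
1,1,12,11,0.34,Sarapiqui
2,1,4,4,0.25,Sarapiqui
3,1,10,9,0.29,Sarapiqui
4,1,24,24,0.28,Carara
5,1,10,10,0.31,Carara
6,1,5,4,0.38,Carara
7,2,6,3,0.23,Carara
8,1,6,3,0.22,Carara
9,1,6,5,0.42,Carara
10,1,4,0,0.44,Carara
11,1,4,0,0.51,Sarapiqui
12,1,5,5,0.19,Carara
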