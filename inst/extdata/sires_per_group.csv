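group_id,n_offspring,n_fathers
1,11,3
2,4,1
3,9,6
4,24,7
5,10,4
6,4,4
7,3,3
8,3,3
9,5,3
10,4,3
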